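#' Shapley additive explanations for fitted tree models
#'
#' Attributes each prediction to the features as Shapley values of the
#' interventional game `v(S) = E_b[f(x_S : b)]`, where the expectation runs
#' over a background table and `x_S : b` takes the explained observation's
#' values on the coalition `S` and the background row's values elsewhere.
#' The base value is the average model output over the background table and
#' every observation's attributions satisfy additivity:
#' `base_value + sum(phi) = model_output`.
#'
#' Three estimators are provided:
#' \describe{
#'   \item{`sampling`}{Permutation sampling (the default). Background rows
#'     are cycled so that each is used equally often, which makes
#'     additivity hold to floating-point accuracy rather than only in
#'     expectation. Deterministic under `seed`.}
#'   \item{`exact_subsets`}{Exhaustive enumeration of all feature
#'     coalitions; exact, limited to at most 12 features.}
#'   \item{`tree_path`}{Exact per-tree computation from the leaf paths
#'     (each leaf induces an AND-game over the path's features with a
#'     closed-form Shapley value). Available for the decision tree and the
#'     forest, whose outputs are additive across trees; not for boosting,
#'     whose logistic link breaks per-tree additivity.}
#' }
#'
#' @param model A `fitted_model` from [train()].
#' @param background Feature table defining the base value (conventionally
#'   the training table).
#' @param targets Feature table of observations to explain.
#' @param method `"sampling"`, `"exact_subsets"` or `"tree_path"`.
#' @param n_samples For `sampling`: requested number of permutations,
#'   rounded up to a multiple of the background size (default 200).
#' @param seed RNG seed for `sampling`.
#' @return An object of class `shap_explanation`: `base_value`, `phi`
#'   (targets x features matrix), `model_output` (vector), `features`,
#'   `method`, `flavour` (always `"interventional"`).
#' @export
shap_values <- function(model, background, targets,
                        method = c("sampling", "exact_subsets", "tree_path"),
                        n_samples = 200, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(model, "fitted_model"))
  Xb <- check_schema(model, background)
  Xt <- check_schema(model, targets)
  p <- ncol(Xb)
  feats <- model$features
  f <- function(X) {
    colnames(X) <- feats
    predict_proba(model, as.data.frame(X))
  }
  base_value <- mean(f(Xb))
  out_t <- f(Xt)

  phi <- switch(method,
    sampling = shap_sampling(f, Xb, Xt, n_samples, seed),
    exact_subsets = {
      if (p > 12)
        stop("exact_subsets supports at most 12 features (got ", p, ")",
             call. = FALSE)
      shap_exact(f, Xb, Xt)
    },
    tree_path = shap_tree_path(model, Xb, Xt))
  colnames(phi) <- feats
  structure(list(base_value = base_value, phi = phi,
                 model_output = out_t, features = feats, method = method,
                 flavour = "interventional"),
            class = "shap_explanation")
}

# Permutation-sampling estimator. Cycling the background rows an equal
# number of times per target makes sum(phi) equal f(x) - mean(f(bg)) exactly.
shap_sampling <- function(f, Xb, Xt, n_samples, seed) {
  set.seed(seed)
  p <- ncol(Xb)
  nb <- nrow(Xb)
  nt <- nrow(Xt)
  n_perm <- max(1L, ceiling(n_samples / nb)) * nb
  phi <- matrix(0, nt, p)
  for (ti in seq_len(nt)) {
    x <- Xt[ti, ]
    perms <- replicate(n_perm, sample.int(p), simplify = FALSE)
    bg_rows <- rep_len(seq_len(nb), n_perm)
    big <- matrix(0, n_perm * (p + 1L), p)
    for (s in seq_len(n_perm)) {
      row <- Xb[bg_rows[s], ]
      off <- (s - 1L) * (p + 1L)
      big[off + 1L, ] <- row
      for (j in seq_len(p)) {
        row[perms[[s]][j]] <- x[perms[[s]][j]]
        big[off + 1L + j, ] <- row
      }
    }
    pred <- f(big)
    for (s in seq_len(n_perm)) {
      off <- (s - 1L) * (p + 1L)
      d <- diff(pred[off + seq_len(p + 1L)])
      phi[ti, perms[[s]]] <- phi[ti, perms[[s]]] + d
    }
    phi[ti, ] <- phi[ti, ] / n_perm
  }
  phi
}

# Exhaustive coalition enumeration (interventional): exact for <= 12
# features. v(S) is averaged over all background rows.
shap_exact <- function(f, Xb, Xt) {
  p <- ncol(Xb)
  nb <- nrow(Xb)
  nt <- nrow(Xt)
  masks <- 0:(2^p - 1)
  member <- vapply(seq_len(p),
                   function(j) bitwAnd(masks, bitwShiftL(1L, j - 1L)) > 0,
                   logical(length(masks)))
  size <- rowSums(member)
  # weight |S|! (p-|S|-1)! / p!; the full coalition never appears as a
  # "without j" set, so give it weight 0 instead of factorial(-1)
  wgt <- numeric(length(size))
  sub <- size < p
  wgt[sub] <- factorial(size[sub]) * factorial(p - size[sub] - 1) /
    factorial(p)
  phi <- matrix(0, nt, p)
  for (ti in seq_len(nt)) {
    x <- Xt[ti, ]
    v <- numeric(length(masks))
    for (mi in seq_along(masks)) {
      Xs <- Xb
      on <- which(member[mi, ])
      if (length(on)) Xs[, on] <- matrix(x[on], nb, length(on), byrow = TRUE)
      v[mi] <- mean(f(Xs))
    }
    for (j in seq_len(p)) {
      without <- which(!member[, j])     # positions, i.e. mask value + 1
      with_j <- without + 2^(j - 1)
      phi[ti, j] <- sum(wgt[without] * (v[with_j] - v[without]))
    }
  }
  phi
}

# Exact interventional Shapley values from tree paths. For one tree, one
# background row r and one target x, each leaf contributes its value times
# the Shapley value of the AND-game "all features where only x passes are
# in S, none where only r passes": phi_i = val * (u-1)! v! / (u+v)! for the
# u must-have features, and -val * (v-1)! u! / (u+v)! for the v must-nots.
shap_tree_path <- function(model, Xb, Xt) {
  fam <- model$spec$family
  if (fam == "gradient_boosting")
    stop("tree_path is not available for gradient boosting; ",
         "use `sampling`", call. = FALSE)
  p <- ncol(Xb)
  nt_trees <- length(model$trees)
  phi <- matrix(0, nrow(Xt), p)

  leaf_paths <- function(tree) {
    paths <- list()
    walk <- function(node, lo, hi) {
      v <- tree$var[node + 1L]
      if (v < 0) {
        paths[[length(paths) + 1L]] <<- list(value = tree$value[node + 1L],
                                             lo = lo, hi = hi)
        return(invisible())
      }
      thr <- tree$thr[node + 1L]
      hi2 <- hi; hi2[v + 1L] <- min(hi2[v + 1L], thr)
      walk(tree$left[node + 1L], lo, hi2)
      lo2 <- lo; lo2[v + 1L] <- max(lo2[v + 1L], thr)
      walk(tree$right[node + 1L], lo2, hi)
    }
    walk(0L, rep(-Inf, p), rep(Inf, p))
    paths
  }

  for (tr in model$trees) {
    paths <- leaf_paths(tr)
    for (leaf in paths) {
      val <- if (fam == "random_forest")
        (leaf$value >= 0.5) / nt_trees else leaf$value
      if (val == 0) next
      used <- which(is.finite(leaf$lo) | is.finite(leaf$hi))
      pass <- function(X) {
        ok <- matrix(TRUE, nrow(X), length(used))
        for (jj in seq_along(used)) {
          j <- used[jj]
          ok[, jj] <- X[, j] > leaf$lo[j] & X[, j] <= leaf$hi[j]
        }
        ok
      }
      pass_t <- pass(Xt)
      pass_b <- pass(Xb)
      all_t <- rowSums(pass_t) == length(used)
      for (bi in seq_len(nrow(Xb))) {
        pb <- pass_b[bi, ]
        for (ti in seq_len(nrow(Xt))) {
          pt <- pass_t[ti, ]
          if (any(!pt & !pb)) next          # leaf unreachable
          U <- used[pt & !pb]
          V <- used[!pt & pb]
          u <- length(U); v <- length(V)
          if (u == 0 && v == 0) next        # reached regardless: base only
          if (u > 0)
            phi[ti, U] <- phi[ti, U] +
              val * factorial(u - 1) * factorial(v) / factorial(u + v)
          if (v > 0)
            phi[ti, V] <- phi[ti, V] -
              val * factorial(v - 1) * factorial(u) / factorial(u + v)
        }
      }
    }
  }
  phi / nrow(Xb)
}

#' Extract one observation's attribution
#'
#' @param explanation A `shap_explanation`.
#' @param i Observation (row) index.
#' @return An object of class `attribution`: `base_value`, `phi` (named
#'   vector), `model_output`.
#' @export
attribution <- function(explanation, i) {
  stopifnot(inherits(explanation, "shap_explanation"))
  structure(list(base_value = explanation$base_value,
                 phi = stats::setNames(explanation$phi[i, ],
                                       explanation$features),
                 model_output = explanation$model_output[i]),
            class = "attribution")
}

#' Global signed feature importance
#'
#' Ranks features by mean absolute attribution over the explained
#' observations; ties are broken alphabetically. The direction flag is the
#' sign of the mean signed attribution (positive features push predictions
#' towards the effective class).
#'
#' @param explanation A `shap_explanation` (non-empty).
#' @return A data frame with `feature`, `mean_abs_phi`, `mean_phi`,
#'   `direction` (`"positive"` / `"negative"` / `"none"`), `rank`; ordered
#'   by rank.
#' @export
global_importance <- function(explanation) {
  stopifnot(inherits(explanation, "shap_explanation"))
  if (nrow(explanation$phi) == 0L)
    stop("no attributions to summarise", call. = FALSE)
  mabs <- colMeans(abs(explanation$phi))
  msgn <- colMeans(explanation$phi)
  ord <- order(-mabs, explanation$features)
  out <- data.frame(feature = explanation$features[ord],
                    mean_abs_phi = mabs[ord], mean_phi = msgn[ord],
                    direction = ifelse(msgn[ord] > 0, "positive",
                                       ifelse(msgn[ord] < 0, "negative",
                                              "none")),
                    rank = seq_along(ord))
  rownames(out) <- NULL
  out
}

#' Force-plot decomposition of one attribution
#'
#' Splits the attribution into the features pushing the prediction above
#' the base value and those pushing it below, each ordered by absolute
#' contribution; the two push lists sum to `model_output - base_value`.
#'
#' @param attr An [attribution()].
#' @return A list with `positive` and `negative` data frames (`feature`,
#'   `phi`), `net` (= `model_output - base_value`), `base_value`,
#'   `model_output`.
#' @export
force_decomposition <- function(attr) {
  stopifnot(inherits(attr, "attribution"))
  phi <- attr$phi[attr$phi != 0]
  mk <- function(v) {
    v <- v[order(-abs(v))]
    data.frame(feature = names(v), phi = unname(v))
  }
  list(positive = mk(phi[phi > 0]), negative = mk(phi[phi < 0]),
       net = attr$model_output - attr$base_value,
       base_value = attr$base_value, model_output = attr$model_output)
}

#' Write attributions as long-format CSV
#'
#' @param explanation A `shap_explanation`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_attributions <- function(explanation, path) {
  long <- data.frame(
    row_id = rep(seq_len(nrow(explanation$phi)),
                 times = length(explanation$features)),
    feature = rep(explanation$features, each = nrow(explanation$phi)),
    phi = as.vector(explanation$phi),
    base_value = explanation$base_value,
    model_output = rep(explanation$model_output,
                       times = length(explanation$features)))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
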