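# Permutation-based multivariate statistics: Euclidean distance matrices,
# principal coordinates, one- and two-factor PERMANOVA with pairwise
# a posteriori t comparisons, and canonical analysis of principal
# coordinates (CAP-style canonical correlation between two ordinations).

#' Euclidean distance matrix between rows
#'
#' @param data Numeric matrix or data.frame (objects x variables).
#' @return Full symmetric distance matrix with zero diagonal; row names
#'   carried over as object ids.
#' @export
euclidean_distance <- function(data) {
  data <- as.matrix(data)
  if (any(!is.finite(data))) stop("data must be finite")
  d <- as.matrix(stats::dist(data, method = "euclidean"))
  dimnames(d) <- list(rownames(data), rownames(data))
  d
}

check_distance_matrix <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (any(D < 0) || any(abs(diag(D)) > 1e-12) ||
      any(abs(D - t(D)) > 1e-8)) {
    stop("not a valid distance matrix (symmetric, non-negative, zero diagonal)")
  }
  D
}

# Gower-centred matrix G = (I - 11'/n) (-D^2/2) (I - 11'/n)
gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' Principal coordinates analysis
#'
#' Eigen-decomposition of the Gower-centred matrix of `-D^2/2`.
#' Eigenvalues are reported in descending order (negative ones included);
#' coordinate axes are returned for positive eigenvalues only, and axes
#' with `|eigenvalue| < 1e-10` are dropped. For Euclidean-embeddable
#' distances the inter-object distances reconstructed from all positive
#' axes equal the input.
#'
#' @param D Distance matrix.
#' @return List of class `pcoa_result`: `eigenvalues` (descending),
#'   `vectors` (objects x retained axes, scaled by `sqrt(eigenvalue)`),
#'   `prop_explained` (share of positive-eigenvalue variation per
#'   retained axis).
#' @export
pcoa <- function(D) {
  D <- check_distance_matrix(D)
  G <- gower_center(D)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  vals <- e$values
  keep <- vals > 1e-10
  vecs <- e$vectors[, keep, drop = FALSE]
  coords <- sweep(vecs, 2, sqrt(vals[keep]), `*`)
  if (ncol(coords) > 0L) {
    dimnames(coords) <- list(rownames(D),
                             paste0("Axis", seq_len(ncol(coords))))
  }
  structure(list(
    eigenvalues = vals,
    vectors = coords,
    prop_explained = if (any(keep)) vals[keep] / sum(vals[keep]) else numeric()
  ), class = "pcoa_result")
}

# enumerate distinct permutations of a label vector (multiset
# permutations); only called when the count is known to be small
multiset_permutations <- function(labels) {
  n <- length(labels)
  lev <- sort(unique(labels))
  counts <- as.integer(table(factor(labels, levels = lev)))
  out <- list()
  recur <- function(prefix, counts) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (i in seq_along(lev)) {
      if (counts[i] > 0L) {
        counts[i] <- counts[i] - 1L
        recur(c(prefix, lev[i]), counts)
        counts[i] <- counts[i] + 1L
      }
    }
  }
  recur(character(0), counts)
  out
}

n_multiset_permutations <- function(labels) {
  counts <- table(labels)
  exp(lgamma(length(labels) + 1) - sum(lgamma(counts + 1)))
}

# sums of squares and pseudo-F statistics for a (possibly permuted)
# Gower-centred matrix under main-effects factors
permanova_stats <- function(G, design) {
  n <- nrow(G)
  ss_total <- sum(diag(G))
  hats <- lapply(design, function(f) {
    X <- stats::model.matrix(~f)
    X %*% solve(crossprod(X), t(X))
  })
  X_full <- stats::model.matrix(~., data = design)
  H_full <- X_full %*% solve(crossprod(X_full), t(X_full))
  df_fac <- vapply(design, function(f) nlevels(f) - 1L, integer(1))
  df_res <- n - 1L - sum(df_fac)
  ss_res <- sum((diag(n) - H_full) * G)
  stats_per_factor <- vapply(seq_along(design), function(j) {
    if (length(design) == 1L) {
      ss_j <- sum(hats[[j]] * G)
    } else {
      # improvement of the full main-effects model over the model
      # without factor j (order-independent for crossed designs)
      X_red <- stats::model.matrix(~., data = design[-j])
      H_red <- X_red %*% solve(crossprod(X_red), t(X_red))
      ss_j <- sum((H_full - H_red) * G)
    }
    c(ss_j, (ss_j / df_fac[j]) / (ss_res / df_res))
  }, numeric(2))
  list(ss = stats_per_factor[1, ], F = stats_per_factor[2, ],
       ss_total = ss_total, ss_res = ss_res,
       df = df_fac, df_res = df_res)
}

as_design <- function(design, n) {
  if (is.factor(design) || is.atomic(design)) {
    design <- data.frame(factor = factor(design))
  }
  design <- as.data.frame(design)
  design[] <- lapply(design, function(f) factor(as.character(f)))
  if (nrow(design) != n) stop("design must have one row per object")
  if (ncol(design) < 1L || ncol(design) > 2L) {
    stop("design must have 1 or 2 factors")
  }
  for (nm in names(design)) {
    f <- design[[nm]]
    if (nlevels(f) < 2L) stop("factor '", nm, "' has a single level")
    if (any(table(f) < 2L)) {
      stop("every level of factor '", nm, "' needs >= 2 objects")
    }
  }
  design
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Distance-based pseudo-F tests for one factor or for the main effects of
#' two crossed factors, with significance from unrestricted permutation of
#' object labels. When the number of distinct label permutations does not
#' exceed `n_perm` the permutation distribution is enumerated exhaustively
#' (then exact and deterministic, `p = #\{F* >= F\} / #permutations`);
#' otherwise `n_perm` random permutations are drawn and
#' `p = (1 + #\{F* >= F\}) / (1 + n_perm)`.
#'
#' On univariate data with Euclidean distances the one-factor pseudo-F
#' equals the classical one-way ANOVA F.
#'
#' @param D Distance matrix.
#' @param design Factor (or data.frame of 1-2 factors), one row/element
#'   per object of `D`.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional integer seed for the random permutations.
#' @return List of class `permanova_result`: `table` (data.frame with
#'   factor, df, SS, pseudo_F, p_value), `ss_total`, `ss_within`,
#'   `df_residual`, `n_perm_used`, `exhaustive`, `seed`.
#' @export
permanova <- function(D, design, n_perm = 9999L, seed = NULL) {
  D <- check_distance_matrix(D)
  n <- nrow(D)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  design <- as_design(design, n)
  G <- gower_center(D)
  obs <- permanova_stats(G, design)
  joint <- do.call(paste, c(design, list(sep = "\r")))
  n_distinct <- n_multiset_permutations(joint)
  exhaustive <- n_distinct <= n_perm
  eps <- 1e-12
  if (exhaustive) {
    # enumerate distinct arrangements of the joint labels
    perms <- multiset_permutations(joint)
    count_ge <- numeric(length(obs$F))
    for (pm in perms) {
      dd <- design
      parts <- strsplit(pm, "\r", fixed = TRUE)
      for (j in seq_along(design)) {
        dd[[j]] <- factor(vapply(parts, `[[`, character(1), j),
                          levels = levels(design[[j]]))
      }
      st <- permanova_stats(G, dd)
      count_ge <- count_ge + (st$F >= obs$F - eps)
    }
    p <- count_ge / length(perms)
    n_used <- length(perms)
  } else {
    if (!is.null(seed)) {
      old <- globalenv()$.Random.seed
      on.exit(restore_rng(old), add = TRUE)
      set.seed(seed)
    }
    count_ge <- numeric(length(obs$F))
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      st <- permanova_stats(G[idx, idx, drop = FALSE], design)
      count_ge <- count_ge + (st$F >= obs$F - eps)
    }
    p <- (1 + count_ge) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(
    table = data.frame(factor = names(design), df = obs$df, SS = obs$ss,
                       pseudo_F = obs$F, p_value = p,
                       stringsAsFactors = FALSE),
    ss_total = obs$ss_total, ss_within = obs$ss_res,
    df_residual = obs$df_res, n_perm_used = n_used,
    exhaustive = exhaustive, seed = seed
  ), class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s, %d permutations)\n",
              if (x$exhaustive) "exhaustive" else "random", x$n_perm_used))
  print(x$table, row.names = FALSE)
  cat(sprintf("Residual df %d, SS_within %.4g, SS_total %.4g\n",
              x$df_residual, x$ss_within, x$ss_total))
  invisible(x)
}

#' Pairwise a posteriori comparisons by PERMANOVA t-statistic
#'
#' For each pair of levels of a single factor, runs a one-factor PERMANOVA
#' on the corresponding sub-matrix and reports `t = sqrt(pseudo-F)` with
#' its permutation p-value. With only two levels, `t^2` equals the global
#' pseudo-F.
#'
#' @param D Distance matrix.
#' @param design Single factor over the objects of `D`.
#' @param n_perm Number of permutations per pair.
#' @param seed Optional integer seed.
#' @return Data.frame with columns `level_1`, `level_2`, `t`, `p_value`,
#'   `exhaustive`.
#' @export
pairwise_posthoc <- function(D, design, n_perm = 9999L, seed = NULL) {
  D <- check_distance_matrix(D)
  f <- factor(as.character(if (is.data.frame(design)) design[[1]]
                           else design))
  if (nlevels(f) < 2L) stop("need >= 2 factor levels")
  lev <- levels(f)
  pairs <- utils::combn(lev, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    sel <- f %in% pairs[, i]
    res <- permanova(D[sel, sel, drop = FALSE], droplevels(f[sel]),
                     n_perm = n_perm,
                     seed = if (is.null(seed)) NULL else seed + i)
    data.frame(level_1 = pairs[1, i], level_2 = pairs[2, i],
               t = sqrt(max(res$table$pseudo_F[1], 0)),
               p_value = res$table$p_value[1],
               exhaustive = res$exhaustive, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Canonical analysis of principal coordinates (CAP correlation)
#'
#' Measures the multivariate correlation between two distance matrices
#' over the same objects: each matrix is ordinated by [pcoa()], a number
#' of leading axes is retained, and canonical correlation analysis is run
#' between the two retained score sets. The leading squared canonical
#' correlation (`delta2_1`) is tested by permuting the object order of the
#' second score set.
#'
#' By default the retained axes are the smallest number explaining at
#' least 90 percent of the positive-eigenvalue variation, capped at
#' `n - 2` (the cap prevents trivially perfect correlations when as many
#' axes as objects are used).
#'
#' @param D1,D2 Distance matrices over the same objects.
#' @param m_axes Number of retained axes for both ordinations, or `NULL`
#'   for the automatic choice.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @return List of class `cap_result`: `squared_correlations` (descending),
#'   `delta2_1`, `p_value`, `m_axes` (axes retained per matrix),
#'   `n_perm`, `seed`.
#' @export
cap_correlation <- function(D1, D2, m_axes = NULL, n_perm = 999L,
                            seed = NULL) {
  D1 <- check_distance_matrix(D1)
  D2 <- check_distance_matrix(D2)
  n <- nrow(D1)
  if (nrow(D2) != n) stop("D1 and D2 must cover the same objects")
  if (!is.null(m_axes) && m_axes >= n) stop("m_axes must be < n")
  pick_axes <- function(p) {
    if (!is.null(m_axes)) return(min(m_axes, ncol(p$vectors)))
    if (ncol(p$vectors) == 0L) stop("no positive principal-coordinate axes")
    m <- which(cumsum(p$prop_explained) >= 0.9)[1]
    max(1L, min(m, n - 2L, ncol(p$vectors)))
  }
  p1 <- pcoa(D1); p2 <- pcoa(D2)
  m1 <- pick_axes(p1); m2 <- pick_axes(p2)
  S1 <- p1$vectors[, seq_len(m1), drop = FALSE]
  S2 <- p2$vectors[, seq_len(m2), drop = FALSE]
  cc <- stats::cancor(S1, S2)
  d2 <- cc$cor^2
  obs <- d2[1]
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  b <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n)
    cp <- stats::cancor(S1, S2[idx, , drop = FALSE])
    if (cp$cor[1]^2 >= obs - 1e-12) b <- b + 1L
  }
  structure(list(
    squared_correlations = d2, delta2_1 = obs,
    p_value = (1 + b) / (1 + n_perm),
    m_axes = c(m1, m2), n_perm = n_perm, seed = seed
  ), class = "cap_result")
}

#' @export
print.cap_result <- function(x, ...) {
  cat(sprintf(
    "CAP: first squared canonical correlation %.4f (p = %.4g, %d/%d axes)\n",
    x$delta2_1, x$p_value, x$m_axes[1], x$m_axes[2]))
  invisible(x)
}

# restore (or remove) the global RNG state saved before seeding
restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
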