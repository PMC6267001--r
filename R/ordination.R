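## Bray-Curtis dissimilarity, principal-coordinates analysis, and canonical
## analysis of principal coordinates (distance-based RDA) with permutation
## tests for odor intensity, age, sampling time, and sex.

#' Bray-Curtis dissimilarity between samples
#'
#' `d(u, v) = 1 - 2 * sum(min(u_i, v_i)) / sum(u_i + v_i)`, bounded in
#' `[0, 1]` for nonnegative abundances.
#'
#' @param x Samples x features abundance matrix (nonnegative).
#' @return A `dist` object.
#' @export
bray_curtis <- function(x) {
  if (any(x < 0)) {
    stop_skinmwas("bray_curtis: negative abundances", "skinmwas_error_config")
  }
  zero <- rowSums(x) == 0
  if (any(zero)) {
    stop_skinmwas(
      paste0("bray_curtis: all-zero sample(s): ",
             paste(head(rownames(x)[zero], 5), collapse = ", ")),
      "skinmwas_error_degenerate")
  }
  vegan::vegdist(x, method = "bray")
}

#' Principal-coordinates analysis
#'
#' Classical scaling: eigendecomposition of the double-centered
#' `-d^2 / 2` matrix. Negative eigenvalues are reported, not corrected;
#' coordinates are returned for the positive axes only.
#'
#' @param d A `dist` or symmetric distance matrix.
#' @return A list with `eigenvalues` (all, non-increasing) and
#'   `coordinates` (samples x positive axes).
#' @export
pcoa <- function(d) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  fit <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig))
  coords <- fit$points[, seq_len(sum(pos)), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(eigenvalues = eig, coordinates = coords)
}

#' Canonical analysis of principal coordinates (distance-based RDA)
#'
#' Regresses the positive-eigenvalue principal coordinates of the
#' dissimilarity on the constraint variables and eigen-analyzes the fitted
#' values (vegan's `capscale`). Significance of the constraint set comes
#' from a permutation test of the pseudo-F statistic under row permutation
#' of the constraints, `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`;
#' deterministic given `seed`.
#'
#' @param d A `dist` of Bray-Curtis dissimilarities.
#' @param data Data frame of constraint variables aligned to the samples
#'   of `d` (numeric odor intensity; factors for age group, timepoint,
#'   sex).
#' @param constraints Character vector naming the columns of `data` to use.
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Integer seed for the permutation stream.
#' @return A `cap_result` list: `eigenvalues` (constrained),
#'   `sample_scores`, `biplot_scores`, `pseudo_F`, `p_value`, `inertia`
#'   (total over positive axes, constrained, unconstrained), `n_perm`,
#'   `dropped` (aliased constraint columns, if any).
#' @export
cap_analysis <- function(d, data, constraints, n_perm = 999, seed = 1) {
  if (n_perm < 99) {
    stop_skinmwas("cap_analysis: n_perm must be >= 99",
                  "skinmwas_error_config")
  }
  missing_c <- setdiff(constraints, names(data))
  if (length(missing_c)) {
    stop_skinmwas(paste0("cap_analysis: unknown constraint(s): ",
                         paste(missing_c, collapse = ", ")),
                  "skinmwas_error_config")
  }
  df <- as.data.frame(data[, constraints, drop = FALSE])
  for (j in names(df)) if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
  fml <- stats::as.formula(paste("d ~", paste(constraints, collapse = " + ")))
  mod <- vegan::capscale(fml, data = df)
  dropped <- tryCatch(stats::alias(mod, names = TRUE),
                      error = function(e) character(0))
  if (length(dropped)) {
    rlang::warn(paste0("cap_analysis: collinear constraints dropped: ",
                       paste(dropped, collapse = ", ")))
  }
  an <- withr::with_seed(derive_seed(seed, "ordination"), {
    stats::anova(mod, permutations = n_perm)
  })
  structure(list(
    eigenvalues = mod$CCA$eig,
    sample_scores = vegan::scores(mod, display = "sites",
                                  choices = seq_len(max(1,
                                    min(2, length(mod$CCA$eig))))),
    biplot_scores = mod$CCA$biplot,
    pseudo_F = an$F[1],
    p_value = an$`Pr(>F)`[1],
    inertia = c(total = mod$CCA$tot.chi + mod$CA$tot.chi,
                constrained = mod$CCA$tot.chi,
                unconstrained = mod$CA$tot.chi),
    n_perm = n_perm,
    dropped = dropped,
    model = mod
  ), class = "cap_result")
}

#' @export
print.cap_result <- function(x, ...) {
  cat("<cap_result>\n")
  cat("  constrained axes:", length(x$eigenvalues), "\n")
  cat("  inertia: total", signif(x$inertia["total"], 4),
      "| constrained", signif(x$inertia["constrained"], 4),
      sprintf("(%.1f%%)", 100 * x$inertia["constrained"] /
                x$inertia["total"]), "\n")
  cat("  pseudo-F:", signif(x$pseudo_F, 4),
      " permutation p:", format.pval(x$p_value), "(", x$n_perm,
      "permutations )\n")
  invisible(x)
}
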