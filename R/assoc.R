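## Dual-mode association core: cross-sectional Spearman vs. odor intensity,
## longitudinal paired Wilcoxon across timepoints, unpaired group tests,
## Benjamini-Hochberg FDR, and Table-1-style significance/direction calls.

#' Spearman rank correlation with odor-style p-values
#'
#' Rho uses average-rank (midrank) ties handling. The two-sided p-value is
#' exact (full permutation null) for n <= 9 without ties and uses the
#' t-distribution approximation otherwise.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return A list with `rho` and `p`.
#' @export
spearman_assoc <- function(x, y) {
  if (length(x) != length(y)) {
    stop_skinmwas("spearman_assoc: unequal lengths", "skinmwas_error_config")
  }
  if (length(x) < 4) {
    stop_skinmwas("spearman_assoc: need n >= 4", "skinmwas_error_degenerate")
  }
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop_skinmwas("spearman_assoc: constant vector, correlation undefined",
                  "skinmwas_error_degenerate")
  }
  n <- length(x)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = (n <= 9 && !ties)))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

# exact conditional signed-rank null by enumerating sign flips on midranks;
# two-sided tail measured symmetrically around the null mean of V
signed_rank_enum_p <- function(d) {
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  ev <- sum(r) / 2
  mean(abs(vs - ev) >= abs(v_obs - ev) - 1e-12)
}

#' Wilcoxon signed-rank test for paired pre/post abundances
#'
#' Zero differences are dropped (classic Wilcoxon). The two-sided p-value
#' is exact for up to 25 nonzero untied pairs; for tied samples of up to 12
#' nonzero pairs it is computed by exact enumeration of all sign
#' assignments on midranks; otherwise a tie-corrected normal approximation
#' with continuity correction is used. All differences zero is a degenerate
#' (not an error) outcome with `p = 1`.
#'
#' @param before,after Paired numeric vectors (same subjects, same order).
#' @return A list with `statistic` (V, sum of positive ranks), `p`, and
#'   `n_used` (nonzero pairs).
#' @export
wilcoxon_signed_rank <- function(before, after) {
  if (length(before) != length(after)) {
    stop_skinmwas("wilcoxon_signed_rank: unequal lengths",
                  "skinmwas_error_pairing")
  }
  d <- after - before
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, p = 1, n_used = 0L, degenerate = TRUE))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  if (!ties && n <= 25) {
    p <- suppressWarnings(wilcox.test(d, exact = TRUE)$p.value)
  } else if (n <= 12) {
    p <- signed_rank_enum_p(d)
  } else {
    ev <- n * (n + 1) / 4
    nties <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                    sum(nties^3 - nties) / 48)
    z <- v - ev
    z <- (z - sign(z) * 0.5) / sigma  # continuity correction
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(statistic = v, p = p, n_used = n, degenerate = FALSE)
}

# exact conditional rank-sum null by enumerating group assignments
rank_sum_enum_p <- function(a, b) {
  r <- rank(c(a, b))
  m <- length(a)
  w_obs <- sum(r[seq_len(m)])
  combs <- utils::combn(length(r), m)
  ws <- colSums(matrix(r[combs], nrow = m))
  p_lo <- mean(ws <= w_obs + 1e-12)
  p_hi <- mean(ws >= w_obs - 1e-12)
  min(1, 2 * min(p_lo, p_hi))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided; exact for small untied samples, exact by enumeration for
#' small tied samples, tie-corrected normal approximation with continuity
#' correction otherwise.
#'
#' @param a,b Numeric vectors (both nonempty).
#' @return A list with `statistic` (Mann-Whitney U for the first group) and
#'   `p`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!length(a) || !length(b)) {
    stop_skinmwas("wilcoxon_rank_sum: empty group", "skinmwas_error_config")
  }
  ties <- anyDuplicated(c(a, b)) > 0
  u <- sum(rank(c(a, b))[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  if (!ties && length(a) <= 50 && length(b) <= 50) {
    p <- suppressWarnings(wilcox.test(a, b, exact = TRUE)$p.value)
  } else if (ties && choose(length(a) + length(b), length(a)) <= 20000) {
    p <- rank_sum_enum_p(a, b)
  } else {
    p <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                      correct = TRUE)$p.value)
  }
  list(statistic = u, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (NAs preserved).
#' @return Adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) {
    stop_skinmwas("bh_adjust: p-values outside [0, 1]",
                  "skinmwas_error_config")
  }
  p.adjust(pvals, method = "BH")
}

#' Feature-wise dual-mode association with odor intensity
#'
#' For each feature (row of `features`), over the samples of one body site
#' and one age stratum (`youth` pools children and teenagers; both
#' timepoints pooled): Spearman's rho and p against odor intensity
#' (cross-sectional), and a Wilcoxon signed-rank p over subject-paired
#' 1 h/8 h values (longitudinal). P-values are BH-adjusted across features
#' separately per test. A feature is flagged significant when
#' `q_spearman < q_threshold` and `|rho| > rho_threshold`; the direction
#' arrow is the sign of the median paired (post - pre) difference.
#' Features constant across the stratum's samples are excluded with a
#' logged reason (see `attr(result, "excluded")`), not an error.
#'
#' @param features Numeric matrix, features x samples.
#' @param meta Cohort metadata tibble.
#' @param site Body-site label to analyze.
#' @param stratum `"youth"`, `"children"` or `"teens"`.
#' @param q_threshold FDR gate (default 0.1).
#' @param rho_threshold Absolute-correlation gate (default 0.2).
#' @return A tibble with one row per tested feature: `feature`, `site`,
#'   `stratum`, `n_samples`, `n_pairs`, `rho`, `p_spearman`, `q_spearman`,
#'   `statistic_wilcoxon`, `p_wilcoxon`, `q_wilcoxon`, `direction`
#'   (`"up"`, `"down"`, `"none"`), `significant`.
#' @export
associate_features <- function(features, meta, site,
                               stratum = c("youth", "children", "teens"),
                               q_threshold = 0.1, rho_threshold = 0.2) {
  stratum <- match.arg(stratum)
  groups <- if (stratum == "youth") c("children", "teens") else stratum
  m <- meta[meta$site == site & meta$age_group %in% groups, ]
  align_samples(features, m, "feature table")
  if (length(unique(m$subject_id)) < 3) {
    stop_skinmwas("fewer than 3 subjects in stratum", "skinmwas_error_config")
  }
  x <- features[, m$sample_id, drop = FALSE]

  tps <- sort(unique(m$timepoint))
  pair_wide <- tidyr::pivot_wider(
    m[, c("subject_id", "timepoint", "sample_id")],
    names_from = timepoint, values_from = sample_id)
  if (length(tps) == 2) {
    unpaired <- pair_wide$subject_id[
      is.na(pair_wide[[tps[1]]]) | is.na(pair_wide[[tps[2]]])]
    if (length(unpaired)) {
      stop_skinmwas(
        paste0("unpaired subjects for signed-rank test: ",
               paste(unpaired, collapse = ", ")),
        "skinmwas_error_pairing")
    }
    pre_ids <- pair_wide[[tps[1]]]
    post_ids <- pair_wide[[tps[2]]]
  } else {
    pre_ids <- post_ids <- character(0)
  }

  res <- vector("list", nrow(x))
  excluded <- character(0)
  for (i in seq_len(nrow(x))) {
    v <- x[i, ]
    if (length(unique(v)) == 1) {
      excluded <- c(excluded, rownames(x)[i])
      next
    }
    sp <- spearman_assoc(v, m$odor_intensity[match(colnames(x),
                                                   m$sample_id)])
    if (length(pre_ids)) {
      wr <- wilcoxon_signed_rank(features[rownames(x)[i], pre_ids],
                                 features[rownames(x)[i], post_ids])
      med <- median(features[rownames(x)[i], post_ids] -
                      features[rownames(x)[i], pre_ids])
    } else {
      wr <- list(statistic = NA_real_, p = NA_real_, n_used = 0L)
      med <- 0
    }
    res[[i]] <- tibble::tibble(
      feature = rownames(x)[i], site = site, stratum = stratum,
      n_samples = ncol(x), n_pairs = wr$n_used,
      rho = sp$rho, p_spearman = sp$p,
      statistic_wilcoxon = wr$statistic, p_wilcoxon = wr$p,
      direction = if (med > 0) "up" else if (med < 0) "down" else "none"
    )
  }
  out <- dplyr::bind_rows(res)
  if (length(excluded)) {
    rlang::inform(paste0("associate_features: excluded ", length(excluded),
                         " constant feature(s) at (", site, ", ", stratum,
                         ")"))
  }
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      feature = character(), site = character(), stratum = character(),
      n_samples = integer(), n_pairs = integer(), rho = numeric(),
      p_spearman = numeric(), statistic_wilcoxon = numeric(),
      p_wilcoxon = numeric(), direction = character())
  }
  out$q_spearman <- if (nrow(out)) bh_adjust(out$p_spearman) else numeric(0)
  out$q_wilcoxon <- if (nrow(out)) bh_adjust(out$p_wilcoxon) else numeric(0)
  out$significant <- !is.na(out$q_spearman) &
    out$q_spearman < q_threshold & abs(out$rho) > rho_threshold
  out <- out[, c("feature", "site", "stratum", "n_samples", "n_pairs",
                 "rho", "p_spearman", "q_spearman", "statistic_wilcoxon",
                 "p_wilcoxon", "q_wilcoxon", "direction", "significant")]
  attr(out, "excluded") <- excluded
  out
}

#' Association across all three age strata
#'
#' Runs [associate_features()] for `youth`, `children` and `teens` at one
#' site and binds the results. The BH family is per (site, stratum, test),
#' as in the per-stratum adjusted p-values of the study's species table.
#'
#' @inheritParams associate_features
#' @return A tibble (rows = features x strata).
#' @export
associate_all_strata <- function(features, meta, site, q_threshold = 0.1,
                                 rho_threshold = 0.2) {
  dplyr::bind_rows(lapply(c("youth", "children", "teens"), function(s) {
    associate_features(features, meta, site, s, q_threshold, rho_threshold)
  }))
}

#' Render an association table in the style of the study's species table
#'
#' Adjusted p-values above the significance threshold are rendered `n.s.`,
#' direction as arrows; raw numerics stay in the machine-readable result.
#'
#' @param assoc Tibble from [associate_features()].
#' @param q_threshold Rendering threshold for `n.s.` (default 0.1).
#' @return A tibble with display columns.
#' @export
format_association_table <- function(assoc, q_threshold = 0.1) {
  fmt_q <- function(q) {
    ifelse(is.na(q) | q > q_threshold, "n.s.", signif(q, 2))
  }
  tibble::tibble(
    feature = assoc$feature, site = assoc$site, stratum = assoc$stratum,
    spearman_rho = round(assoc$rho, 2),
    spearman_q = fmt_q(assoc$q_spearman),
    direction = unname(c(up = "↑", down = "↓", none = "-")[
      assoc$direction]),
    wilcoxon_q = fmt_q(assoc$q_wilcoxon)
  )
}
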