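#' Normalize and summarize a microarray expression matrix
#'
#' Raw intensities are log2-transformed, quantile normalized (columns end up
#' with identical sorted value distributions) and, where a probe is
#' represented by several rows, summarized by median polish (overall effect
#' plus column effects; tolerance 1e-6, at most 10 iterations).
#'
#' @param raw numeric matrix of positive raw intensities (rows = probe
#'   replicates/spots, columns = samples).
#' @param probe_ids probe identifier per row (default rownames); rows sharing
#'   an id are summarized together.
#' @param log2_transform apply log2 first (default TRUE; set FALSE when the
#'   input is already on the log scale).
#' @return probes x samples matrix of normalized log2 expression.
#' @export
normalize_expression <- function(raw, probe_ids = rownames(raw),
                                 log2_transform = TRUE) {
  raw <- as.matrix(raw)
  if (log2_transform) {
    if (any(raw <= 0)) stop("raw intensities must be positive")
    raw <- log2(raw)
  }
  qn <- limma::normalizeQuantiles(raw)
  if (is.null(probe_ids)) probe_ids <- as.character(seq_len(nrow(qn)))
  if (!anyDuplicated(probe_ids)) {
    rownames(qn) <- probe_ids
    return(qn)
  }
  ids <- unique(probe_ids)
  out <- matrix(NA_real_, nrow = length(ids), ncol = ncol(qn),
                dimnames = list(ids, colnames(qn)))
  for (id in ids) {
    sub <- qn[probe_ids == id, , drop = FALSE]
    if (nrow(sub) == 1L) {
      out[id, ] <- sub
    } else {
      mp <- medpolish(sub, eps = 1e-6, maxiter = 10L, trace.iter = FALSE)
      out[id, ] <- mp$overall + mp$col
    }
  }
  out
}

#' Signal-to-noise statistic
#'
#' `(mean(treated) - mean(control)) / (sd(treated) + sd(control))`, with each
#' standard deviation floored at `max(eps, floor_frac * |group mean|)` so the
#' statistic stays defined when replicates are identical.
#'
#' @param treated,control numeric vectors of replicate values (>= 2 each).
#' @param eps absolute sd floor (default 0.01).
#' @param floor_frac relative sd floor as a fraction of the group mean
#'   magnitude (default 0, i.e. the plain formula unless an sd vanishes).
#' @return the signal-to-noise value.
#' @export
snr_statistic <- function(treated, control, eps = 0.01, floor_frac = 0) {
  stopifnot(length(treated) >= 2, length(control) >= 2)
  sdt <- max(sd(treated), eps, floor_frac * abs(mean(treated)))
  sdc <- max(sd(control), eps, floor_frac * abs(mean(control)))
  if (sdt + sdc == 0) stop("zero denominator: both sds vanish and the floor is disabled")
  (mean(treated) - mean(control)) / (sdt + sdc)
}

## vectorized over matrix rows
snr_rows <- function(mat, treated_cols, control_cols, eps = 0.01, floor_frac = 0) {
  mt <- rowMeans(mat[, treated_cols, drop = FALSE])
  mc <- rowMeans(mat[, control_cols, drop = FALSE])
  sdt <- apply(mat[, treated_cols, drop = FALSE], 1, sd)
  sdc <- apply(mat[, control_cols, drop = FALSE], 1, sd)
  sdt <- pmax(sdt, eps, floor_frac * abs(mt))
  sdc <- pmax(sdc, eps, floor_frac * abs(mc))
  (mt - mc) / (sdt + sdc)
}

#' Permutation p-values for the signal-to-noise statistic
#'
#' The null distribution is built by permuting sample labels. With
#' `pool_probes = TRUE` (default) null statistics from all probes are pooled
#' into a single empirical distribution; otherwise each probe is compared
#' only with its own permuted values. `exhaustive = TRUE` enumerates every
#' distinct relabeling (including the identity) instead of random sampling
#' and reports exact enumeration tail proportions; random sampling uses the
#' add-one estimator `(1 + #{null >= obs}) / (1 + n_perm)`.
#'
#' @param mat probes x samples matrix of normalized log2 expression.
#' @param groups character vector over columns: "treated" or "control".
#' @param n_perm number of random permutations (default 10000).
#' @param seed RNG seed for random permutations.
#' @param pool_probes pool null statistics across probes (default TRUE).
#' @param exhaustive enumerate all relabelings instead of sampling.
#' @param eps,floor_frac see [snr_statistic()].
#' @return data frame with `probe`, `snr`, `p_left`, `p_right`, `p_two`.
#' @export
permutation_pvalues <- function(mat, groups, n_perm = 10000L, seed = 1L,
                                pool_probes = TRUE, exhaustive = FALSE,
                                eps = 0.01, floor_frac = 0) {
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) == length(groups), all(groups %in% c("treated", "control")))
  if (!exhaustive && n_perm < 1) stop("n_perm must be >= 1")
  tc <- which(groups == "treated"); cc <- which(groups == "control")
  obs <- snr_rows(mat, tc, cc, eps, floor_frac)
  nt <- length(tc); ns <- ncol(mat)
  if (exhaustive) {
    combos <- utils::combn(ns, nt)
    null <- apply(combos, 2, function(t_idx) {
      snr_rows(mat, t_idx, setdiff(seq_len(ns), t_idx), eps, floor_frac)
    })
    null <- matrix(null, nrow = nrow(mat))
    if (pool_probes) {
      pool <- as.numeric(null)
      p_right <- vapply(obs, function(o) mean(pool >= o), 0)
      p_left <- vapply(obs, function(o) mean(pool <= o), 0)
    } else {
      p_right <- rowMeans(null >= obs)
      p_left <- rowMeans(null <= obs)
    }
  } else {
    null <- matrix(NA_real_, nrow = nrow(mat), ncol = n_perm)
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        t_idx <- sample.int(ns, nt)
        null[, b] <- snr_rows(mat, t_idx, setdiff(seq_len(ns), t_idx),
                              eps, floor_frac)
      }
    })
    if (pool_probes) {
      pool <- as.numeric(null)
      np <- length(pool)
      p_right <- vapply(obs, function(o) (1 + sum(pool >= o)) / (1 + np), 0)
      p_left <- vapply(obs, function(o) (1 + sum(pool <= o)) / (1 + np), 0)
    } else {
      p_right <- (1 + rowSums(null >= obs)) / (1 + n_perm)
      p_left <- (1 + rowSums(null <= obs)) / (1 + n_perm)
    }
  }
  probes <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  data.frame(probe = probes, snr = obs, p_left = p_left, p_right = p_right,
             p_two = pmin(1, 2 * pmin(p_left, p_right)),
             stringsAsFactors = FALSE)
}

#' Fold changes on the linear scale from log2 expression
#'
#' `FC = 2^(mean_treated - mean_control)`, sign-folded so that repression of
#' half appears as -2 and `abs(fold_change)` can be thresholded directly.
#'
#' @param mat probes x samples matrix of log2 expression.
#' @param groups "treated"/"control" per column.
#' @return numeric vector of signed linear fold changes.
#' @export
fold_changes <- function(mat, groups) {
  mat <- as.matrix(mat)
  d <- rowMeans(mat[, groups == "treated", drop = FALSE]) -
    rowMeans(mat[, groups == "control", drop = FALSE])
  ifelse(d >= 0, 2^d, -2^(-d))
}

#' Differential-expression statistics table
#'
#' Convenience wrapper: signal-to-noise statistic, permutation p-values and
#' signed fold change per probe, with the significance gate
#' `p <= p_max & |FC| >= min_abs_fc` applied.
#'
#' @param mat probes x samples matrix of normalized log2 expression.
#' @param groups "treated"/"control" per column.
#' @param p_max nominal p-value threshold (default 0.01).
#' @param min_abs_fc absolute linear fold-change threshold (default 1.2).
#' @param p_column which p-value the gate uses (default "p_two").
#' @inheritParams permutation_pvalues
#' @return data frame with `probe`, `snr`, `fold_change`, `p_left`,
#'   `p_right`, `p_two`, `significant`.
#' @export
de_stats <- function(mat, groups, n_perm = 10000L, seed = 1L,
                     pool_probes = TRUE, exhaustive = FALSE,
                     p_max = 0.01, min_abs_fc = 1.2, p_column = "p_two") {
  pv <- permutation_pvalues(mat, groups, n_perm = n_perm, seed = seed,
                            pool_probes = pool_probes, exhaustive = exhaustive)
  pv$fold_change <- fold_changes(mat, groups)
  pv$significant <- pv[[p_column]] <= p_max & abs(pv$fold_change) >= min_abs_fc
  pv[, c("probe", "snr", "fold_change", "p_left", "p_right", "p_two", "significant")]
}

#' Gate a DE table and intersect with target gene lists
#'
#' @param stats DE table from [de_stats()] (or any data frame with `probe`,
#'   a p-value column and `fold_change`).
#' @param target_gene_lists named list of character vectors of gene/probe
#'   identifiers (e.g. predicted targets of individual miRNAs).
#' @param p_max,min_abs_fc,p_column gate parameters as in [de_stats()].
#' @return list with `significant` (character vector) and `intersections`
#'   (named list of per-list intersections with the significant set).
#' @export
gate_and_intersect <- function(stats, target_gene_lists = list(),
                               p_max = 0.01, min_abs_fc = 1.2,
                               p_column = "p_two") {
  sig <- stats$probe[stats[[p_column]] <= p_max & abs(stats$fold_change) >= min_abs_fc]
  list(significant = sig,
       intersections = lapply(target_gene_lists, intersect, y = sig))
}
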