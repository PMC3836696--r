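# Resampling machinery for propensity uncertainty and significance:
# leave-10%-out percentile bounds, validity-label permutation null,
# set-size convergence, fixed-size sampling tables, subgroup-vs-random
# comparison. All operations are deterministic under a fixed seed.

#' Resampling configuration
#'
#' @param n_reps Number of replicates.
#' @param leave_out_fraction Fraction of proteins left out per replicate
#'   (default 0.10).
#' @param seed Integer seed.
#' @param percentile_bounds Lower/upper percentile bounds (default 2.5 and
#'   97.5, i.e. the 95% interval), computed empirically with linear
#'   interpolation.
#' @param keep_replicates Retain the per-replicate propensity matrix.
#' @return A `bp_resample_config` list.
#' @export
resample_config <- function(n_reps = 1000L, leave_out_fraction = 0.10,
                            seed = 1L, percentile_bounds = c(2.5, 97.5),
                            keep_replicates = FALSE) {
  stopifnot(n_reps >= 1, leave_out_fraction >= 0, leave_out_fraction < 1,
            length(percentile_bounds) == 2)
  structure(list(n_reps = as.integer(n_reps),
                 leave_out_fraction = leave_out_fraction,
                 seed = as.integer(seed),
                 percentile_bounds = percentile_bounds,
                 keep_replicates = isTRUE(keep_replicates)),
            class = "bp_resample_config")
}

# Per-protein aggregates for one validity class: summed site counts per
# protein and the has-site indicator implementing the inclusion rule
# ("only proteins that contained at least one site of that type").
class_aggregates <- function(dataset, validity) {
  info <- dataset$site_info
  sel <- info$validity == validity
  P <- nrow(dataset$surface_counts)
  bs <- matrix(0, P, 20, dimnames = list(NULL, AA3))
  if (any(sel)) {
    agg <- rowsum(dataset$site_counts[sel, , drop = FALSE],
                  group = info$protein[sel])
    bs[as.integer(rownames(agg)), ] <- agg
  }
  list(bs = bs, has_site = tabulate(info$protein[sel], P) > 0)
}

# Fast propensity vector for a protein subset (integer indices or logical).
prop_vec <- function(bs_per_protein, has_site, surface_counts, keep) {
  if (is.logical(keep)) keep <- which(keep)
  inc <- keep[has_site[keep]]
  if (!length(inc)) return(NULL)
  bs <- colSums(bs_per_protein[inc, , drop = FALSE])
  ps <- colSums(surface_counts[inc, , drop = FALSE])
  tb <- sum(bs); tp <- sum(ps)
  if (tb == 0 || tp == 0) return(NULL)
  p <- (bs / tb) / (ps / tp)
  p[ps == 0] <- NA_real_
  p
}

#' Full-set pooled propensity of a composition dataset
#'
#' Applies the per-class inclusion rule (only proteins with at least one
#' site of the class enter the surface denominator) and returns pooled
#' Eq.-style propensities.
#'
#' @param dataset A `bp_composition`.
#' @param validity `"valid"` or `"invalid"`.
#' @param proteins Optional protein subset (integer indices).
#' @return A `bp_propensity` data frame (see [compute_propensity()]).
#' @export
composition_propensity <- function(dataset, validity = "valid",
                                   proteins = NULL) {
  stopifnot(inherits(dataset, "bp_composition"))
  if (is.null(proteins)) proteins <- seq_len(nrow(dataset$surface_counts))
  agg <- class_aggregates(dataset, validity)
  inc <- proteins[agg$has_site[proteins]]
  if (!length(inc)) stop("no proteins with sites of class '", validity, "'")
  info <- dataset$site_info
  n_sites <- sum(info$validity == validity & info$protein %in% inc)
  bs <- accumulate_frequencies(agg$bs[inc, , drop = FALSE], "binding_site",
                               class = "all", validity = validity,
                               n_structures = length(inc),
                               n_sites = n_sites)
  ps <- accumulate_frequencies(dataset$surface_counts[inc, , drop = FALSE],
                               "protein_surface", class = "all",
                               validity = validity,
                               n_structures = length(inc))
  compute_propensity(bs, ps)
}

percentiles <- function(x, bounds) {
  stats::quantile(x, probs = bounds / 100, na.rm = TRUE, names = FALSE,
                  type = 7)
}

#' Leave-k-out propensity resampling
#'
#' Recomputes the pooled propensity `n_reps` times, each time on a random
#' (1 - f) fraction of the proteins (the resampling unit is the protein, not
#' the site), and reports per-residue median, percentile bounds and standard
#' deviation. Replicates whose retained subset yields no surface counts are
#' discarded with a warning.
#'
#' @param dataset A `bp_composition`.
#' @param cfg A [resample_config()].
#' @param validity `"valid"` or `"invalid"`.
#' @return A `bp_resample_result`: data frame per residue (median, lower,
#'   upper, sd) plus metadata; replicates retained if requested.
#' @export
leave_k_out <- function(dataset, cfg = resample_config(),
                        validity = "valid") {
  stopifnot(inherits(dataset, "bp_composition"),
            inherits(cfg, "bp_resample_config"))
  set.seed(cfg$seed)
  P <- nrow(dataset$surface_counts)
  agg <- class_aggregates(dataset, validity)
  n_keep <- max(1L, round((1 - cfg$leave_out_fraction) * P))
  reps <- matrix(NA_real_, cfg$n_reps, 20, dimnames = list(NULL, AA3))
  discarded <- 0L
  for (r in seq_len(cfg$n_reps)) {
    keep <- if (n_keep == P) seq_len(P) else sort(sample.int(P, n_keep))
    p <- prop_vec(agg$bs, agg$has_site, dataset$surface_counts, keep)
    if (is.null(p)) discarded <- discarded + 1L else reps[r, ] <- p
  }
  if (discarded > 0)
    warning(discarded, " replicate(s) discarded (no surface counts)")
  reps <- reps[rowSums(!is.na(reps)) > 0, , drop = FALSE]
  out <- data.frame(
    resname = AA3,
    median = apply(reps, 2, stats::median, na.rm = TRUE),
    lower = apply(reps, 2, function(x)
      percentiles(x, cfg$percentile_bounds)[1]),
    upper = apply(reps, 2, function(x)
      percentiles(x, cfg$percentile_bounds)[2]),
    sd = apply(reps, 2, stats::sd, na.rm = TRUE),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(list(summary = out, validity = validity, cfg = cfg,
                 n_used = nrow(reps), n_discarded = discarded,
                 replicates = if (cfg$keep_replicates) reps else NULL),
            class = "bp_resample_result")
}

#' Validity-label permutation null for propensity ratios
#'
#' Shuffles the valid/invalid labels over sites `n_shuffles` times
#' (a permutation of the label multiset, so class proportions are
#' maintained; protein membership is untouched), recomputes pooled
#' propensities and valid/invalid ratios each time, and reports per residue
#' the mean, min and max of the null ratios next to the observed ratio.
#' A residue is flagged by the envelope rule when its observed ratio falls
#' outside [min, max] of the null; the conventional fixed thresholds
#' (ratio > 1.2 or < 0.8) are reported alongside for comparison, not used
#' as the decision rule.
#'
#' @param dataset A `bp_composition` with both validity classes present.
#' @param n_shuffles Number of label permutations (default 1000).
#' @param seed Integer seed.
#' @return A `bp_shuffle_null`: data frame per residue (observed ratio, null
#'   mean/min/max, envelope and fixed-threshold flags) plus metadata.
#' @export
shuffle_validity_null <- function(dataset, n_shuffles = 1000L, seed = 1L) {
  stopifnot(inherits(dataset, "bp_composition"))
  info <- dataset$site_info
  if (!all(c("valid", "invalid") %in% info$validity))
    stop("both validity classes must be present")
  set.seed(seed)
  sc <- dataset$site_counts
  prot <- info$protein
  surf <- dataset$surface_counts
  labels <- info$validity

  ratio_for <- function(lab) {
    iv <- which(lab == "valid"); ii <- which(lab == "invalid")
    bs_v <- colSums(sc[iv, , drop = FALSE])
    bs_i <- colSums(sc[ii, , drop = FALSE])
    ps_v <- colSums(surf[unique(prot[iv]), , drop = FALSE])
    ps_i <- colSums(surf[unique(prot[ii]), , drop = FALSE])
    pv <- (bs_v / sum(bs_v)) / (ps_v / sum(ps_v))
    pi_ <- (bs_i / sum(bs_i)) / (ps_i / sum(ps_i))
    pv[ps_v == 0] <- NA_real_; pi_[ps_i == 0] <- NA_real_
    pv / pi_
  }

  observed <- ratio_for(labels)
  null <- matrix(NA_real_, n_shuffles, 20, dimnames = list(NULL, AA3))
  for (r in seq_len(n_shuffles))
    null[r, ] <- ratio_for(sample(labels))
  out <- data.frame(
    resname = AA3,
    observed_ratio = unname(observed),
    null_mean = apply(null, 2, mean, na.rm = TRUE),
    null_min = apply(null, 2, min, na.rm = TRUE),
    null_max = apply(null, 2, max, na.rm = TRUE),
    stringsAsFactors = FALSE)
  out$significant_envelope <- !is.na(out$observed_ratio) &
    (out$observed_ratio < out$null_min | out$observed_ratio > out$null_max)
  out$significant_fixed <- !is.na(out$observed_ratio) &
    (out$observed_ratio > 1.2 | out$observed_ratio < 0.8)
  rownames(out) <- NULL
  structure(list(summary = out, n_shuffles = n_shuffles, seed = seed),
            class = "bp_shuffle_null")
}

#' Set-size convergence scan
#'
#' For a ladder of subset sizes (default: every 1% of the protein set),
#' draws `reps_per_point` random subsets without replacement, computes the
#' pooled propensity for each, and reports per-residue dispersion (standard
#' deviation) and mean per size. Dispersion shrinks with size; rare residues
#' stay noisy to much larger sizes than frequent ones.
#'
#' @param dataset A `bp_composition`.
#' @param validity `"valid"` or `"invalid"`.
#' @param step_fraction Size increment as a fraction of the full set.
#' @param reps_per_point Random subsets per size.
#' @param seed Integer seed.
#' @param sizes Optional explicit vector of subset sizes (overrides
#'   `step_fraction`); must be strictly increasing.
#' @return A `bp_convergence`: long data frame (size, resname, mean, sd).
#' @export
convergence_scan <- function(dataset, validity = "valid",
                             step_fraction = 0.01, reps_per_point = 100L,
                             seed = 1L, sizes = NULL) {
  stopifnot(inherits(dataset, "bp_composition"))
  P <- nrow(dataset$surface_counts)
  if (is.null(sizes)) {
    step <- round(P * step_fraction)
    if (step < 1) {
      warning("step smaller than 1 structure; coerced to 1")
      step <- 1L
    }
    sizes <- unique(pmin(P, seq(step, P, by = step)))
  }
  stopifnot(all(diff(sizes) > 0), all(sizes >= 1), all(sizes <= P))
  set.seed(seed)
  agg <- class_aggregates(dataset, validity)
  rows <- list()
  for (s in sizes) {
    reps <- matrix(NA_real_, reps_per_point, 20)
    for (r in seq_len(reps_per_point)) {
      keep <- if (s == P) seq_len(P) else sort(sample.int(P, s))
      p <- prop_vec(agg$bs, agg$has_site, dataset$surface_counts, keep)
      if (!is.null(p)) reps[r, ] <- p
    }
    rows[[length(rows) + 1]] <- data.frame(
      size = s, resname = AA3,
      mean = apply(reps, 2, mean, na.rm = TRUE),
      sd = apply(reps, 2, stats::sd, na.rm = TRUE),
      n_ok = colSums(!is.na(reps)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(curve = out, validity = validity, sizes = sizes,
                 reps_per_point = reps_per_point, seed = seed),
            class = "bp_convergence")
}

#' Fixed-size random-sampling table
#'
#' For each requested subset size and validity class, draws `n_reps` random
#' protein subsets, computes the pooled propensity of each, and tabulates
#' per-residue median, standard deviation and 2.5/97.5 percentiles — the
#' layout used to judge how large a structure set must be before propensity
#' estimates stabilize.
#'
#' @param dataset A `bp_composition`.
#' @param sizes Subset sizes (must not exceed the number of proteins).
#' @param n_reps Samples per size.
#' @param seed Integer seed.
#' @param validities Validity classes to tabulate.
#' @return Long data frame (validity, size, resname, median, sd, lower,
#'   upper).
#' @export
fixed_size_table <- function(dataset, sizes = c(100, 500, 1000, 2000),
                             n_reps = 10000L, seed = 1L,
                             validities = c("valid", "invalid")) {
  stopifnot(inherits(dataset, "bp_composition"))
  P <- nrow(dataset$surface_counts)
  if (any(sizes > P)) stop("requested size exceeds the number of proteins")
  if (n_reps < 2)
    warning("n_reps < 2: standard deviations are undefined")
  set.seed(seed)
  rows <- list()
  for (v in validities) {
    agg <- class_aggregates(dataset, v)
    for (s in sizes) {
      reps <- matrix(NA_real_, n_reps, 20)
      for (r in seq_len(n_reps)) {
        keep <- if (s == P) seq_len(P) else sort(sample.int(P, s))
        p <- prop_vec(agg$bs, agg$has_site, dataset$surface_counts, keep)
        if (!is.null(p)) reps[r, ] <- p
      }
      rows[[length(rows) + 1]] <- data.frame(
        validity = v, size = s, resname = AA3,
        median = apply(reps, 2, stats::median, na.rm = TRUE),
        sd = if (n_reps >= 2) apply(reps, 2, stats::sd, na.rm = TRUE)
             else NA_real_,
        lower = apply(reps, 2, function(x) percentiles(x, c(2.5, 97.5))[1]),
        upper = apply(reps, 2, function(x) percentiles(x, c(2.5, 97.5))[2]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare a subgroup's propensities against matched random sets
#'
#' The subgroup's leave-10%-out percentile bounds are compared with the
#' percentile bounds of pooled propensities from `n_reps` random protein
#' subsets of `matched_size` drawn from the full set. A residue is flagged
#' when the two 95% intervals are disjoint — the strictest criterion, since
#' any overlap withholds the flag.
#'
#' @param dataset A `bp_composition`.
#' @param subgroup Integer indices of the subgroup's proteins.
#' @param matched_size Size of the random comparison sets (default: the
#'   subgroup size); must not exceed the dataset size.
#' @param n_reps Replicates for both samplings.
#' @param seed Integer seed.
#' @param validity Validity class analyzed.
#' @param leave_out_fraction Leave-out fraction for the subgroup bounds.
#' @return Data frame per residue: subgroup median and bounds, random-set
#'   bounds, and the `flagged` indicator.
#' @export
subgroup_vs_random <- function(dataset, subgroup, matched_size = NULL,
                               n_reps = 1000L, seed = 1L,
                               validity = "valid",
                               leave_out_fraction = 0.10) {
  stopifnot(inherits(dataset, "bp_composition"))
  P <- nrow(dataset$surface_counts)
  subgroup <- sort(unique(as.integer(subgroup)))
  stopifnot(all(subgroup >= 1), all(subgroup <= P))
  if (is.null(matched_size)) matched_size <- length(subgroup)
  if (matched_size > P) stop("matched_size exceeds the dataset size")
  set.seed(seed)
  agg <- class_aggregates(dataset, validity)

  # Subgroup leave-k-out bounds.
  n_keep <- max(1L, round((1 - leave_out_fraction) * length(subgroup)))
  sub_reps <- matrix(NA_real_, n_reps, 20)
  for (r in seq_len(n_reps)) {
    keep <- subgroup[sort(sample.int(length(subgroup), n_keep))]
    p <- prop_vec(agg$bs, agg$has_site, dataset$surface_counts, keep)
    if (!is.null(p)) sub_reps[r, ] <- p
  }
  # Random matched-size bounds from the full set.
  rnd_reps <- matrix(NA_real_, n_reps, 20)
  for (r in seq_len(n_reps)) {
    keep <- if (matched_size == P) seq_len(P) else
      sort(sample.int(P, matched_size))
    p <- prop_vec(agg$bs, agg$has_site, dataset$surface_counts, keep)
    if (!is.null(p)) rnd_reps[r, ] <- p
  }
  q <- function(m, pr) apply(m, 2, function(x)
    stats::quantile(x, pr, na.rm = TRUE, names = FALSE))
  out <- data.frame(
    resname = AA3,
    sub_median = apply(sub_reps, 2, stats::median, na.rm = TRUE),
    sub_lower = q(sub_reps, 0.025), sub_upper = q(sub_reps, 0.975),
    rand_lower = q(rnd_reps, 0.025), rand_upper = q(rnd_reps, 0.975),
    stringsAsFactors = FALSE)
  out$flagged <- out$sub_lower > out$rand_upper |
    out$sub_upper < out$rand_lower
  out$flagged[is.na(out$flagged)] <- FALSE
  rownames(out) <- NULL
  out
}
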