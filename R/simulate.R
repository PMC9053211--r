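#' Specification for a synthetic case-control biomarker cohort
#'
#' Describes the generative model used by [simulate_cohort()]: marker
#' concentrations are log2-normal (multivariate normal on the log2 scale
#' with a block correlation structure), with per-cancer mean shifts on a
#' subset of informative markers, per-marker limits of detection placed at
#' a stated quantile of the control distribution, additional
#' missing-at-random masking, and an age covariate whose case distribution
#' sits a few years above the control distribution.
#'
#' @param n_controls number of control subjects (default 184).
#' @param n_per_cancer named integer vector of case counts per cancer type
#'   (default `c(pancreatic = 47, ovarian = 44, bladder = 48)`).
#' @param n_markers number of markers on the panel (default 42).
#' @param informative named list: for each cancer type, the names of the
#'   markers shifted in its cases.
#' @param effect_sizes named numeric: mean log2-scale shift applied to each
#'   cancer's informative markers (a scalar per cancer, or a vector named
#'   by marker).
#' @param base_log2_mean,base_log2_sd control-group mean and SD on the log2
#'   scale, recycled across markers (defaults 6 and 1.5 -- wide,
#'   right-skewed concentration distributions on the natural scale).
#' @param correlation either a full marker-marker correlation matrix or a
#'   list `list(block_size =, rho =)` describing equicorrelated blocks.
#' @param lod_quantile per-marker quantile of the control log2-normal
#'   marginal at which the LOD is placed (scalar or length `n_markers`);
#'   controls fall below their LOD with roughly this probability.
#' @param missing_rate probability a measured cell is masked missing at
#'   random (default 0.02).
#' @param age_params list with `control = c(median, sd, min, max)` and
#'   `case = c(median, sd, min, max)`; defaults put control median near 57
#'   (range 40-71) and case median near 60 (range 21-76).
#' @param stage_counts named list: per cancer, `c(I = , II = )` case counts
#'   by stage; `NULL` splits stages roughly 60/40 at random.
#' @param seed integer seed; the generator is a pure function of the spec
#'   including this seed.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_controls = 184L,
                     n_per_cancer = c(pancreatic = 47L, ovarian = 44L,
                                      bladder = 48L),
                     n_markers = 42L,
                     informative = NULL,
                     effect_sizes = c(pancreatic = 4.0, ovarian = 2.6,
                                      bladder = 1.8),
                     base_log2_mean = 6,
                     base_log2_sd = 1.5,
                     correlation = list(block_size = 6L, rho = 0.3),
                     lod_quantile = 0.10,
                     missing_rate = 0.02,
                     age_params = list(control = c(median = 57, sd = 7,
                                                   min = 40, max = 71),
                                       case = c(median = 60, sd = 11,
                                                min = 21, max = 76)),
                     stage_counts = NULL,
                     seed = 1L) {
  n_markers <- as.integer(n_markers)
  marker_names <- sprintf("EVP%02d", seq_len(n_markers))
  if (is.null(informative)) {
    # 13 informative markers overlapping across the three cancers
    k <- min(13L, n_markers)
    inf_names <- marker_names[seq_len(k)]
    informative <- list(
      pancreatic = inf_names[seq_len(min(8L, k))],
      ovarian = inf_names[intersect(4:11, seq_len(k))],
      bladder = inf_names[intersect(6:13, seq_len(k))])
  }
  spec <- structure(list(
    n_controls = as.integer(n_controls),
    n_per_cancer = n_per_cancer,
    n_markers = n_markers,
    marker_names = marker_names,
    informative = informative,
    effect_sizes = effect_sizes,
    base_log2_mean = rep_len(base_log2_mean, n_markers),
    base_log2_sd = rep_len(base_log2_sd, n_markers),
    correlation = correlation,
    lod_quantile = rep_len(lod_quantile, n_markers),
    missing_rate = missing_rate,
    age_params = age_params,
    stage_counts = stage_counts,
    seed = as.integer(seed)), class = "sim_spec")
  validate_sim_spec(spec)
  spec
}

validate_sim_spec <- function(spec) {
  stopifnot(spec$n_controls >= 1L, all(spec$n_per_cancer >= 1L),
            spec$n_markers >= 1L,
            all(is.finite(unlist(spec$effect_sizes))),
            spec$missing_rate >= 0, spec$missing_rate < 1,
            all(spec$lod_quantile > 0), all(spec$lod_quantile < 1),
            all(names(spec$n_per_cancer) %in% CANCER_LEVELS))
  bad <- setdiff(unlist(spec$informative), spec$marker_names)
  if (length(bad)) {
    stop("informative markers not on the panel: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(spec)
}

# Build the marker-marker correlation matrix from the spec and check PSD.
correlation_from_spec <- function(spec) {
  p <- spec$n_markers
  if (is.matrix(spec$correlation)) {
    C <- spec$correlation
    if (!isTRUE(all.equal(C, t(C))) ||
        min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop("correlation matrix must be symmetric positive semi-definite",
           call. = FALSE)
    }
  } else {
    bs <- spec$correlation$block_size
    rho <- spec$correlation$rho
    if (abs(rho) >= 1) stop("block correlation rho must be in (-1, 1)",
                            call. = FALSE)
    block <- rep(seq_len(ceiling(p / bs)), each = bs)[seq_len(p)]
    C <- outer(block, block, function(a, b) ifelse(a == b, rho, 0))
    diag(C) <- 1
  }
  dimnames(C) <- list(spec$marker_names, spec$marker_names)
  C
}

#' Preset emulating the reference study's cohort structure
#'
#' 184 controls and 47/44/48 pancreatic/ovarian/bladder cases (323
#' subjects), a 42-marker panel with 13 informative markers shared
#' unevenly across the cancers (strong pancreatic shifts, moderate
#' ovarian, weak bladder), stage counts matching the published cohort
#' (pancreatic 22 I / 25 II; ovarian 39 I / 5 II with 26 stage IA and 22
#' serous; bladder 27 I / 21 II), and 8 panel markers censored heavily
#' enough to fall to the <50% prevalence filter.
#'
#' @param seed integer seed stored in the spec.
#' @return A [sim_spec()].
#' @export
study_like_spec <- function(seed = 1L) {
  lodq <- c(rep(0.10, 34), rep(0.70, 8))
  sim_spec(lod_quantile = lodq,
           stage_counts = list(pancreatic = c(I = 22L, II = 25L),
                               ovarian = c(I = 39L, II = 5L),
                               bladder = c(I = 27L, II = 21L)),
           seed = seed)
}

#' Simulate a case-control cohort from a specification
#'
#' Marker values are drawn as `2^x` with `x` multivariate normal on the
#' log2 scale; each cancer's informative markers receive its mean shift.
#' Per-marker LODs are placed deterministically at `lod_quantile` of the
#' control log2-normal marginal. Below-LOD values are reported as drawn
#' (censoring is applied downstream); an additional `missing_rate`
#' fraction of cells is masked `NA` at random. The generator is a pure
#' function of the spec, including its seed.
#'
#' @param spec a [sim_spec()].
#' @return A list with elements `cohort` (a [cohort()]) and `ground_truth`
#'   (the per-cancer informative marker names).
#' @export
simulate_cohort <- function(spec) {
  validate_sim_spec(spec)
  C <- correlation_from_spec(spec)
  p <- spec$n_markers
  Sigma <- diag(spec$base_log2_sd) %*% C %*% diag(spec$base_log2_sd)
  groups <- c(rep("control", spec$n_controls),
              rep(names(spec$n_per_cancer), spec$n_per_cancer))
  n <- length(groups)

  withr::with_seed(spec$seed, {
    Z <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = Sigma)
    log2v <- sweep(Z, 2, spec$base_log2_mean, `+`)
    for (cancer in names(spec$n_per_cancer)) {
      inf <- spec$informative[[cancer]]
      if (!length(inf)) next
      eff <- spec$effect_sizes[[cancer]]
      if (is.null(names(eff))) eff <- stats::setNames(rep_len(eff, length(inf)), inf)
      rows <- which(groups == cancer)
      cols <- match(names(eff), spec$marker_names)
      log2v[rows, cols] <- sweep(log2v[rows, cols, drop = FALSE], 2, eff, `+`)
    }
    vals <- 2^log2v
    if (spec$missing_rate > 0) {
      vals[runif(length(vals)) < spec$missing_rate] <- NA_real_
    }
    subjects <- simulate_subjects(spec, groups)
    markers <- data.frame(
      name = spec$marker_names,
      lod = 2^qnorm(spec$lod_quantile, spec$base_log2_mean,
                    spec$base_log2_sd),
      units = "pg/mL",
      panel = "EV-protein",
      stringsAsFactors = FALSE)
    co <- cohort(subjects, markers, vals)
  })
  list(cohort = co,
       ground_truth = spec$informative)
}

# Subject metadata: ages from clipped normals matching the target medians,
# sex balanced in controls and all-female ovarian cases, stages per the
# configured counts. Runs inside the generator's seeded block.
simulate_subjects <- function(spec, groups) {
  n <- length(groups)
  is_case <- groups != "control"
  ap <- spec$age_params
  draw_age <- function(m, prm) {
    round(pmin(prm["max"], pmax(prm["min"], rnorm(m, prm["median"], prm["sd"]))))
  }
  age <- numeric(n)
  age[!is_case] <- draw_age(sum(!is_case), ap$control)
  age[is_case] <- draw_age(sum(is_case), ap$case)

  sex <- character(n)
  ctrl <- which(!is_case)
  sex[ctrl] <- sample(rep(c("M", "F"), length.out = length(ctrl)))
  for (cancer in names(spec$n_per_cancer)) {
    rows <- which(groups == cancer)
    if (cancer == "ovarian") {
      sex[rows] <- "F"
    } else {
      sex[rows] <- sample(c("M", "F"), length(rows), replace = TRUE)
    }
  }

  stage <- rep(NA_character_, n)
  sub_stage <- rep(NA_character_, n)
  histology <- rep(NA_character_, n)
  for (cancer in names(spec$n_per_cancer)) {
    rows <- which(groups == cancer)
    sc <- spec$stage_counts[[cancer]]
    if (is.null(sc)) {
      n1 <- round(0.6 * length(rows))
      sc <- c(I = n1, II = length(rows) - n1)
    }
    stopifnot(sum(sc) == length(rows))
    stage[rows] <- sample(rep(c("I", "II"), times = sc))
    if (cancer == "ovarian") {
      st1 <- rows[stage[rows] == "I"]
      n_ia <- min(26L, length(st1))
      sub_stage[sample(st1, n_ia)] <- "IA"
      histology[sample(rows, min(22L, length(rows)))] <- "serous"
    }
  }

  data.frame(id = sprintf("S%03d", seq_len(n)),
             group = groups,
             stage = stage,
             sub_stage = sub_stage,
             histology = histology,
             age = age,
             sex = sex,
             stringsAsFactors = FALSE)
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf("<sim_spec> %d controls + cases (%s), %d markers, seed %d\n",
              x$n_controls,
              paste(sprintf("%s=%d", names(x$n_per_cancer), x$n_per_cancer),
                    collapse = ", "),
              x$n_markers, x$seed))
  cat("  informative:",
      paste(sprintf("%s=%d", names(x$informative),
                    lengths(x$informative)), collapse = ", "), "\n")
  invisible(x)
}
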