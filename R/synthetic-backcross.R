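# Synthetic N2 backcross generator: genotypes under a Haldane map and
# longitudinal diabetes phenotypes with one planted additive QTL.

#' Haldane map function
#'
#' Converts a genetic distance in centimorgan into a recombination fraction
#' under the Haldane (no-interference) model, `r = (1 - exp(-2 d / 100)) / 2`.
#'
#' @param d_cM numeric vector of genetic distances (cM), finite and >= 0.
#' @return recombination fractions in `[0, 0.5)`, monotone increasing in
#'   `d_cM`.
#' @examples
#' haldane_recombination(c(0, 10, 50))
#' @export
haldane_recombination <- function(d_cM) {
  .assert(is.numeric(d_cM) && length(d_cM) >= 1, "d_cM must be numeric")
  .assert(all(is.finite(d_cM)) && all(d_cM >= 0),
          "genetic distances must be finite and >= 0")
  0.5 * (1 - exp(-2 * d_cM / 100))
}

#' Simulate genotypes of an N2 backcross
#'
#' Offspring of an (A x B) F1 backcrossed to A are, at every locus, either
#' homozygous A/A (coded 0) or heterozygous A/B (coded 1), segregating 1:1.
#' The first marker of each chromosome is drawn by a fair coin; each
#' subsequent marker switches state with the Haldane recombination fraction
#' of the inter-marker cM distance, which generates realistic linkage.
#'
#' @param map a [genetic_map()].
#' @param n number of individuals (>= 2).
#' @param seed integer seed; fixed seed gives reproducible genotypes.
#' @return An integer matrix of class `backcross_genotypes`
#'   (individuals x markers, values 0/1), with individual ids as rownames
#'   and marker ids as colnames.
#' @export
simulate_backcross <- function(map, n, seed = 1L) {
  .assert(inherits(map, "genetic_map"), "map must be a genetic_map")
  .assert(.is_count(n, min = 2L), "n must be an integer >= 2")
  set.seed(.substream(seed, 11L))
  m <- nrow(map)
  geno <- matrix(0L, nrow = n, ncol = m,
                 dimnames = list(sprintf("ind%04d", seq_len(n)),
                                 map$marker_id))
  for (chr in unique(map$chromosome)) {
    idx <- which(map$chromosome == chr)
    g <- stats::rbinom(n, 1L, 0.5)
    geno[, idx[1L]] <- g
    if (length(idx) > 1L) {
      r <- haldane_recombination(diff(map$position_cM[idx]))
      for (j in seq_along(r)) {
        switch_ <- stats::rbinom(n, 1L, r[j])
        g <- as.integer(g != switch_)
        geno[, idx[j + 1L]] <- g
      }
    }
  }
  class(geno) <- c("backcross_genotypes", class(geno))
  geno
}

#' Simulation configuration for the backcross cohort
#'
#' Bundles the parameters of the planted phenotype model.  Weekly random
#' blood glucose of animal `i` at age week `w` is
#' `baseline + (w - first_week) * drift * (1 - g_i * protection)
#'  - additive_effect * g_i + N(0, residual_sd)`,
#' where `g_i` is the 0/1 genotype at the causal marker.  Susceptible
#' homozygotes (`g = 0`) therefore drift towards hyperglycemia while
#' heterozygous carriers of the protective allele stay near baseline.
#' Death is a per-week Bernoulli event with probability
#' `death_prob_per_week` in any week whose glucose exceeds
#' `death_glucose_threshold`; series are truncated at death.
#'
#' Defaults emulate a high-fat-diet NZO-style backcross cohort: 150 males
#' followed weekly from 3 to 20 weeks of age, baseline 150 mg/dL, drift
#' +30 mg/dL/week in susceptible animals (so most homozygous controls pass
#' 500 mg/dL around week 15), a 40 mg/dL protective additive effect,
#' residual SD 40 mg/dL, and an 8%/week death risk above 500 mg/dL.
#'
#' @param n_individuals cohort size.
#' @param causal_marker_id marker carrying the planted QTL.
#' @param additive_effect glucose reduction (mg/dL) per protective allele.
#' @param residual_sd residual glucose SD (mg/dL), > 0.
#' @param weekly_weeks number of weekly measurements (default 18).
#' @param first_week age (weeks) at first measurement (default 3).
#' @param glucose_baseline baseline random blood glucose (mg/dL).
#' @param diabetic_drift glucose drift (mg/dL/week) in susceptible animals.
#' @param protection fraction of the drift removed per protective allele,
#'   in `[0, 1]` (default 1: carriers do not drift).
#' @param death_glucose_threshold glucose (mg/dL) above which death risk
#'   applies.
#' @param death_prob_per_week per-week death probability given glucose above
#'   threshold, in `[0, 1]`.
#' @param seed integer seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 150L,
                       causal_marker_id,
                       additive_effect = 40,
                       residual_sd = 40,
                       weekly_weeks = 18L,
                       first_week = 3L,
                       glucose_baseline = 150,
                       diabetic_drift = 30,
                       protection = 1,
                       death_glucose_threshold = 500,
                       death_prob_per_week = 0.08,
                       seed = 1L) {
  .assert(.is_count(n_individuals, 2L), "n_individuals must be >= 2")
  .assert(is.character(causal_marker_id) && length(causal_marker_id) == 1L,
          "causal_marker_id must be a single marker name")
  .assert(.is_number(additive_effect), "additive_effect must be a number")
  .assert(.is_number(residual_sd) && residual_sd > 0, "residual_sd must be > 0")
  .assert(.is_count(weekly_weeks, 1L), "weekly_weeks must be >= 1")
  .assert(.is_count(first_week, 0L), "first_week must be >= 0")
  .assert(.is_number(glucose_baseline) && glucose_baseline > 0,
          "glucose_baseline must be > 0")
  .assert(.is_number(diabetic_drift), "diabetic_drift must be a number")
  .assert(.is_number(protection) && protection >= 0 && protection <= 1,
          "protection must be in [0, 1]")
  .assert(.is_number(death_glucose_threshold) && death_glucose_threshold > 0,
          "death_glucose_threshold must be > 0")
  .assert(.is_number(death_prob_per_week) &&
            death_prob_per_week >= 0 && death_prob_per_week <= 1,
          "death_prob_per_week must be in [0, 1]")
  structure(list(n_individuals = as.integer(n_individuals),
                 causal_marker_id = causal_marker_id,
                 additive_effect = additive_effect,
                 residual_sd = residual_sd,
                 weekly_weeks = as.integer(weekly_weeks),
                 first_week = as.integer(first_week),
                 glucose_baseline = glucose_baseline,
                 diabetic_drift = diabetic_drift,
                 protection = protection,
                 death_glucose_threshold = death_glucose_threshold,
                 death_prob_per_week = death_prob_per_week,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate longitudinal diabetes phenotypes for a backcross cohort
#'
#' Generates the weekly glucose / body-weight / plasma-insulin series
#' implied by a [sim_config()] on top of simulated genotypes, including the
#' glucose-dependent death process.  Body weight follows an obesity-style
#' growth curve independent of genotype; insulin is sampled at weeks 12 and
#' 15 and elevated in protected carriers.
#'
#' @param genotypes a `backcross_genotypes` matrix.
#' @param cfg a [sim_config()]; `cfg$causal_marker_id` must be a column of
#'   `genotypes`.
#' @return A long-format `data.frame` of class `phenotype_table` with
#'   columns `animal`, `group` (`"N/N"` for genotype 0, `"N/C"` for 1),
#'   `week`, `glucose`, `weight`, `insulin`, `dead` (TRUE on the death-week
#'   row), truncated at death.  Per-animal death weeks (NA = survived) are
#'   attached as attribute `death_week`.
#' @export
simulate_phenotypes <- function(genotypes, cfg) {
  .assert(inherits(genotypes, "backcross_genotypes"),
          "genotypes must come from simulate_backcross()")
  .assert(inherits(cfg, "sim_config"), "cfg must be a sim_config")
  .assert(cfg$causal_marker_id %in% colnames(genotypes),
          sprintf("causal marker '%s' not present in genotypes",
                  cfg$causal_marker_id))
  n <- nrow(genotypes)
  g <- as.integer(genotypes[, cfg$causal_marker_id])
  weeks <- cfg$first_week + seq_len(cfg$weekly_weeks) - 1L
  W <- length(weeks)

  set.seed(.substream(cfg$seed, 23L))
  drift_slope <- cfg$diabetic_drift * (1 - g * cfg$protection)
  mu <- cfg$glucose_baseline +
    outer(drift_slope, weeks - cfg$first_week) -
    cfg$additive_effect * g
  glucose <- mu + matrix(stats::rnorm(n * W, 0, cfg$residual_sd), n, W)
  glucose <- pmax(glucose, 40)  # physiological floor for a live measurement

  # obesity-style growth, genotype-independent
  wt_intercept <- stats::rnorm(n, 18, 1.5)
  weight <- wt_intercept + outer(rep(2.0, n), weeks - cfg$first_week) +
    matrix(stats::rnorm(n * W, 0, 0.8), n, W)

  insulin <- matrix(NA_real_, n, W)
  for (wk in intersect(c(12L, 15L), weeks)) {
    j <- match(wk, weeks)
    insulin[, j] <- pmax(0.2, 2 + 2.5 * g + stats::rnorm(n, 0, 1))
  }

  death_week <- rep(NA_integer_, n)
  death_draw <- matrix(stats::runif(n * W), n, W)
  if (cfg$death_prob_per_week > 0) {
    for (i in seq_len(n)) {
      at_risk <- glucose[i, ] > cfg$death_glucose_threshold
      hit <- which(at_risk & death_draw[i, ] < cfg$death_prob_per_week)
      if (length(hit)) death_week[i] <- weeks[hit[1L]]
    }
  }

  ids <- rownames(genotypes)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    keep <- if (is.na(death_week[i])) rep(TRUE, W) else weeks <= death_week[i]
    wk <- weeks[keep]
    rows[[i]] <- data.frame(
      animal = ids[i],
      group = if (g[i] == 1L) "N/C" else "N/N",
      week = wk,
      glucose = round(glucose[i, keep], 1),
      weight = round(weight[i, keep], 1),
      insulin = round(insulin[i, keep], 2),
      dead = !is.na(death_week[i]) & wk == death_week[i],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(death_week) <- ids
  attr(out, "death_week") <- death_week
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Per-animal death weeks of a phenotype table
#'
#' @param pheno a `phenotype_table`.
#' @return named integer vector, NA for animals alive at study end.
#' @export
death_weeks <- function(pheno) {
  .assert(inherits(pheno, "phenotype_table"), "pheno must be a phenotype_table")
  dw <- attr(pheno, "death_week")
  if (!is.null(dw)) return(dw)
  # reconstruct from the dead flag (e.g. after a file round-trip)
  ids <- unique(pheno$animal)
  if (is.null(pheno$dead)) {
    warning("no death information in phenotype table; treating all as alive")
    return(stats::setNames(rep(NA_integer_, length(ids)), ids))
  }
  dw <- vapply(ids, function(a) {
    sub <- pheno[pheno$animal == a & pheno$dead, "week"]
    if (length(sub)) as.integer(min(sub)) else NA_integer_
  }, integer(1))
  dw
}

#' Per-animal summary phenotype for QTL scanning
#'
#' Collapses the longitudinal glucose series to one value per animal; the
#' mean over observed weeks is the default scan phenotype (robust to death
#' truncation), a single week can be requested instead.
#'
#' @param pheno a `phenotype_table`.
#' @param ids individual ids defining the output order.
#' @param week optional single age week; default averages all observed weeks.
#' @return named numeric vector aligned to `ids` (NA where unobserved).
#' @export
scan_phenotype <- function(pheno, ids, week = NULL) {
  .assert(inherits(pheno, "phenotype_table"), "pheno must be a phenotype_table")
  sub <- if (is.null(week)) pheno else pheno[pheno$week == week, , drop = FALSE]
  means <- tapply(sub$glucose, sub$animal, mean)
  out <- as.numeric(means[ids])
  names(out) <- ids
  out
}
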