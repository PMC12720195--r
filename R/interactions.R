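# Classifier of dual-stress (acidosis x hypoxia) omics responses.
#
# For each protein with log2 abundance responses r_acid, r_hypoxia and
# r_combo (each versus control), additivity predicts
# r_combo = r_acid + r_hypoxia. The departure delta = r_combo - (r_acid +
# r_hypoxia) classifies the interaction: synergistic if the combined response
# exceeds the sum by more than the cutoff (0.5 log2 units), antagonistic if
# it falls short by more, additive otherwise. Records in which nothing
# reaches the significance cutoff are non-significant. NOTE the
# non-significance rule is this package's interpretation (the source
# analysis does not define it operationally): a record is non-significant
# when |r_acid|, |r_hypoxia|, |r_combo| AND |delta| are all below
# `significance_cutoff`.

#' Classify acidosis x hypoxia interaction for log2 responses
#'
#' @param r_acid,r_hypoxia,r_combo log2 abundance responses vs control
#'   (vectorized).
#' @param interaction_cutoff |delta| beyond which an interaction is called
#'   (log2 units; default 0.5).
#' @param significance_cutoff threshold below which a record with no
#'   interaction is called non-significant (default 0.5).
#' @return Factor with levels `additive`, `synergistic`, `antagonistic`,
#'   `nonsignificant` (`NA` for records with missing values).
#' @examples
#' classify_interaction(1, 1, 2)     # additive
#' classify_interaction(1, 1, 2.6)   # synergistic (delta = +0.6)
#' classify_interaction(0.3, -0.4, -0.8)  # antagonistic (delta = -0.7)
#' @export
classify_interaction <- function(r_acid, r_hypoxia, r_combo,
                                 interaction_cutoff = 0.5,
                                 significance_cutoff = 0.5) {
  stopifnot(interaction_cutoff > 0, significance_cutoff > 0)
  n <- max(length(r_acid), length(r_hypoxia), length(r_combo))
  r_acid <- rep_len(r_acid, n)
  r_hypoxia <- rep_len(r_hypoxia, n)
  r_combo <- rep_len(r_combo, n)
  delta <- r_combo - (r_acid + r_hypoxia)
  cls <- rep(NA_character_, n)
  ok <- is.finite(r_acid) & is.finite(r_hypoxia) & is.finite(r_combo)
  cls[ok & delta > interaction_cutoff] <- "synergistic"
  cls[ok & delta < -interaction_cutoff] <- "antagonistic"
  add <- ok & abs(delta) <= interaction_cutoff
  nonsig <- add & abs(r_acid) < significance_cutoff &
    abs(r_hypoxia) < significance_cutoff & abs(r_combo) < significance_cutoff &
    abs(delta) < significance_cutoff
  cls[add] <- "additive"
  cls[nonsig] <- "nonsignificant"
  factor(cls, levels = c("additive", "synergistic", "antagonistic",
                         "nonsignificant"))
}

#' Classify a proteome table of dual-stress responses
#'
#' @param table data.frame with columns `protein_id`, `log2fc_acid`,
#'   `log2fc_hypoxia`, `log2fc_combo` (the TSV layout produced by
#'   [generate_synthetic_proteome()]; read external files with
#'   [read_proteome_tsv()]).
#' @param interaction_cutoff,significance_cutoff see [classify_interaction()].
#' @return List of class `interaction_classification`: `table` (input plus
#'   `expected`, `delta`, `class`), `counts` (named integer vector over the
#'   four classes), `n_skipped` (records with missing values),
#'   `frac_nonadditive_significant` (fraction of significant responses that
#'   are synergistic or antagonistic).
#' @export
classify_table <- function(table, interaction_cutoff = 0.5,
                           significance_cutoff = 0.5) {
  need <- c("log2fc_acid", "log2fc_hypoxia", "log2fc_combo")
  if (!all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "))
  out <- table
  out$expected <- out$log2fc_acid + out$log2fc_hypoxia
  out$delta <- out$log2fc_combo - out$expected
  out$class <- classify_interaction(out$log2fc_acid, out$log2fc_hypoxia,
                                    out$log2fc_combo,
                                    interaction_cutoff, significance_cutoff)
  counts <- table(out$class, useNA = "no")
  counts <- stats::setNames(as.integer(counts), names(counts))
  n_sig <- sum(counts[c("additive", "synergistic", "antagonistic")])
  structure(list(
    table = out,
    counts = counts,
    n_skipped = sum(is.na(out$class)),
    frac_nonadditive_significant =
      if (n_sig > 0) sum(counts[c("synergistic", "antagonistic")]) / n_sig
      else NA_real_),
    class = "interaction_classification")
}

#' @export
print.interaction_classification <- function(x, ...) {
  cat("<interaction_classification>\n")
  print(x$counts)
  if (x$n_skipped > 0) cat("  skipped (missing values):", x$n_skipped, "\n")
  cat(sprintf("  non-additive among significant: %.1f%%\n",
              100 * x$frac_nonadditive_significant))
  invisible(x)
}

#' Read a proteome response table from TSV
#'
#' Expects a header with columns `protein_id`, `log2fc_acid`,
#' `log2fc_hypoxia`, `log2fc_combo`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_proteome_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "log2fc_acid", "log2fc_hypoxia", "log2fc_combo")
  if (!all(need %in% names(tab)))
    stop("TSV must have columns ", paste(need, collapse = ", "))
  tab
}

#' Specification for the synthetic dual-stress proteome generator
#'
#' Defaults emulate the scale and class mixture of the SW1222 proteomic
#' experiment the classifier was built for: ~9400 proteins with class
#' fractions matching its reported partition (28% additive, 9% antagonistic,
#' 6% synergistic, 57% non-significant) and a measurement noise of 0.2 log2
#' units.
#'
#' Per class, noiseless responses are drawn so the class label is recovered
#' exactly at zero noise: significant single-stress effects are signed
#' shifted-exponentials with magnitude >= `effect_floor`; interaction
#' deltas are signed shifted-exponentials with magnitude >=
#' `delta_floor` (> 0.5); non-significant records are truncated normals
#' bounded so that every classification quantity stays below 0.5.
#'
#' @param n_proteins number of records.
#' @param class_fractions named fractions over
#'   `additive`/`antagonistic`/`synergistic`/`nonsignificant`; must sum to 1.
#' @param effect_floor minimum |log2fc| of significant single-stress
#'   responses.
#' @param effect_rate rate of the exponential tail above the floor.
#' @param delta_floor minimum |delta| of planted interactions.
#' @param delta_rate exponential tail rate for |delta|.
#' @param noise_sd measurement noise sd added to each response (log2 units).
#' @param seed integer random seed.
#' @return List of class `synthetic_proteome_spec`.
#' @export
synthetic_proteome_spec <- function(n_proteins = 9354,
                                    class_fractions = c(
                                      additive = 2608 / 9354,
                                      antagonistic = 822 / 9354,
                                      synergistic = 569 / 9354,
                                      nonsignificant = 5355 / 9354),
                                    effect_floor = 0.7, effect_rate = 1.2,
                                    delta_floor = 0.75, delta_rate = 1.5,
                                    noise_sd = 0.2, seed = 1L) {
  stopifnot(n_proteins >= 1,
            abs(sum(class_fractions) - 1) < 1e-8,
            all(class_fractions >= 0),
            setequal(names(class_fractions),
                     c("additive", "antagonistic", "synergistic",
                       "nonsignificant")),
            effect_floor > 0.5, delta_floor > 0.5, noise_sd >= 0)
  structure(list(n_proteins = as.integer(n_proteins),
                 class_fractions = class_fractions,
                 effect_floor = effect_floor, effect_rate = effect_rate,
                 delta_floor = delta_floor, delta_rate = delta_rate,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_proteome_spec")
}

#' Generate a synthetic dual-stress proteome table
#'
#' Reproducible under a fixed seed. At `noise_sd = 0` the planted classes
#' are recovered exactly by [classify_table()]; at the default noise the
#' floors leave a margin of one noise sd or more, so recovery errors stay
#' within binomial range.
#'
#' @param spec a [synthetic_proteome_spec()].
#' @return data.frame with columns `protein_id`, `log2fc_acid`,
#'   `log2fc_hypoxia`, `log2fc_combo`, `planted_class`, `planted_delta`.
#' @export
generate_synthetic_proteome <- function(spec = synthetic_proteome_spec()) {
  stopifnot(inherits(spec, "synthetic_proteome_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  n <- spec$n_proteins
  counts <- round(spec$class_fractions * n)
  # make counts sum to n exactly (largest class absorbs the rounding)
  counts[which.max(counts)] <- counts[which.max(counts)] + n - sum(counts)
  cls <- rep(names(counts), counts)

  signed_shifted_exp <- function(m, floor, rate)
    sample(c(-1, 1), m, replace = TRUE) * (floor + stats::rexp(m, rate))
  # truncated normal on [-b, b]
  tnorm <- function(m, sd, b) {
    x <- stats::qnorm(stats::runif(m, stats::pnorm(-b, 0, sd),
                                   stats::pnorm(b, 0, sd)), 0, sd)
    x
  }

  r_a <- r_h <- delta <- numeric(n)
  sig <- cls != "nonsignificant"
  m <- sum(sig)
  r_a[sig] <- signed_shifted_exp(m, spec$effect_floor, spec$effect_rate)
  r_h[sig] <- signed_shifted_exp(m, spec$effect_floor, spec$effect_rate)
  delta[cls == "additive"] <- 0
  ns <- sum(cls == "synergistic")
  delta[cls == "synergistic"] <-
    spec$delta_floor + stats::rexp(ns, spec$delta_rate)
  na <- sum(cls == "antagonistic")
  delta[cls == "antagonistic"] <-
    -(spec$delta_floor + stats::rexp(na, spec$delta_rate))
  # non-significant: all three responses and delta bounded well below 0.5
  m0 <- sum(!sig)
  r_a[!sig] <- tnorm(m0, 0.1, 0.16)
  r_h[!sig] <- tnorm(m0, 0.1, 0.16)
  delta[!sig] <- tnorm(m0, 0.1, 0.16)
  r_c <- r_a + r_h + delta

  noise <- function(m) stats::rnorm(m, 0, spec$noise_sd)
  out <- data.frame(
    protein_id = sprintf("P%05d", seq_len(n)),
    log2fc_acid = r_a + noise(n),
    log2fc_hypoxia = r_h + noise(n),
    log2fc_combo = r_c + noise(n),
    planted_class = cls,
    planted_delta = delta,
    stringsAsFactors = FALSE)
  # shuffle rows so class is not encoded in row order
  out <- out[sample.int(n), ]
  rownames(out) <- NULL
  out
}
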