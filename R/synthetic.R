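# Synthetic expression-survival cohorts. Three generative structures cover
# the mechanisms a random-bias analysis must distinguish: no structure at
# all (calibration), a pervasive survival-linked meta-gene (positive bias,
# the proliferation-signature explanation), and discrete subclasses with
# broad differential expression (negative bias when per-class survival is
# equal; removable positive bias when it is not).

#' Specify a synthetic cohort
#'
#' Defaults encode the calibration conditions used throughout the package:
#' 300 samples, 2000 genes, exponential event times at baseline hazard
#' 0.01 per day with independent exponential censoring at rate 0.003
#' (expected censored fraction 0.003/0.013 ~ 23%), unit noise SD.
#'
#' @param n_samples,n_genes cohort dimensions.
#' @param structure `"null"` (expression independent of survival),
#'   `"global_signature"` (latent meta-gene drives a fraction of genes and
#'   the hazard), or `"subclasses"` (discrete classes with broad DE and
#'   per-class hazards).
#' @param signature_fraction fraction of genes loading on the latent
#'   meta-gene (global_signature only).
#' @param loading_sd SD of per-gene loadings on the meta-gene.
#' @param n_subclasses,mixing number of subclasses and their mixing
#'   proportions (must sum to 1).
#' @param de_fraction fraction of genes differentially expressed between
#'   subclasses.
#' @param de_effect between-class mean shift in units of `noise_sd`.
#' @param baseline_hazard exponential event rate (per time unit).
#' @param log_hazard_ratio log hazard ratio per unit of the latent score
#'   (global_signature only).
#' @param per_class_log_hazard log hazard offset per subclass.
#' @param censoring_rate rate of the independent exponential censoring.
#' @param noise_sd residual expression noise SD.
#' @param seed integer RNG seed; fixed seed gives a bit-identical cohort.
#' @return an object of class `SyntheticCohortSpec`.
#' @export
cohort_spec <- function(n_samples = 300L, n_genes = 2000L,
                        structure = c("null", "global_signature",
                                      "subclasses"),
                        signature_fraction = 0.3, loading_sd = 1,
                        n_subclasses = 2L,
                        mixing = rep(1 / n_subclasses, n_subclasses),
                        de_fraction = 0.3, de_effect = 2,
                        baseline_hazard = 0.01, log_hazard_ratio = 1,
                        per_class_log_hazard = rep(0, n_subclasses),
                        censoring_rate = 0.003, noise_sd = 1,
                        seed = 1L) {
  structure_ <- match.arg(structure)
  if (!is_count(n_samples)) stop_field("n_samples", "positive integer")
  if (!is_count(n_genes)) stop_field("n_genes", "positive integer")
  if (!is_prob(signature_fraction))
    stop_field("signature_fraction", "must be in [0, 1]")
  if (!is_scalar_num(loading_sd) || loading_sd < 0)
    stop_field("loading_sd", "must be >= 0")
  if (!is_count(n_subclasses)) stop_field("n_subclasses", "integer >= 1")
  if (length(mixing) != n_subclasses || abs(sum(mixing) - 1) > 1e-12 ||
      any(mixing < 0))
    stop_field("mixing", "probability vector of length n_subclasses summing to 1")
  if (!is_prob(de_fraction)) stop_field("de_fraction", "must be in [0, 1]")
  if (!is_scalar_num(de_effect) || de_effect < 0)
    stop_field("de_effect", "must be >= 0")
  if (!is_scalar_num(baseline_hazard) || baseline_hazard <= 0)
    stop_field("baseline_hazard", "must be > 0")
  if (!is_scalar_num(log_hazard_ratio))
    stop_field("log_hazard_ratio", "must be a finite number")
  if (length(per_class_log_hazard) != n_subclasses)
    stop_field("per_class_log_hazard", "length must equal n_subclasses")
  if (!is_scalar_num(censoring_rate) || censoring_rate <= 0)
    stop_field("censoring_rate", "must be > 0")
  if (!is_scalar_num(noise_sd) || noise_sd <= 0)
    stop_field("noise_sd", "must be > 0")
  if (structure_ == "null") {
    if (signature_fraction != 0 || de_fraction != 0) {
      # the null structure is by definition signal-free
      signature_fraction <- 0
      de_fraction <- 0
    }
  }
  structure(list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    structure = structure_, signature_fraction = signature_fraction,
    loading_sd = loading_sd, n_subclasses = as.integer(n_subclasses),
    mixing = as.double(mixing), de_fraction = de_fraction,
    de_effect = de_effect, baseline_hazard = baseline_hazard,
    log_hazard_ratio = log_hazard_ratio,
    per_class_log_hazard = as.double(per_class_log_hazard),
    censoring_rate = censoring_rate, noise_sd = noise_sd,
    seed = as.integer(seed)), class = "SyntheticCohortSpec")
}

#' Generate a synthetic cohort
#'
#' Draws expression, the generative truth, and exponential survival with
#' independent exponential censoring according to the spec. The truth
#' record (latent score, subclass label, signal gene indices) is stored in
#' the cohort so recovery tests cannot drift from what was generated.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `SyntheticCohort`: `expression`
#'   ([expression_matrix()], flagged log-scale since values are Gaussian),
#'   `survival` ([survival_table()]), and `truth` (list with `latent`,
#'   `subclass`, `signal_genes`, per-signal-gene `loadings`, and
#'   `anchor_gene`, the most strongly loaded signature gene — the role
#'   PCNA plays for the proliferation program).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "SyntheticCohortSpec"))
  with_seed(spec$seed, {
    n <- spec$n_samples; m <- spec$n_genes
    gene_ids <- sprintf("g%05d", seq_len(m))
    sample_ids <- sprintf("s%04d", seq_len(n))
    values <- matrix(stats::rnorm(m * n, sd = spec$noise_sd), m, n)
    latent <- rep(0, n)
    subclass <- rep(1L, n)
    signal_genes <- integer(0)
    loadings <- numeric(0)
    anchor_gene <- NA_character_
    log_hr <- rep(0, n)

    if (spec$structure == "global_signature") {
      latent <- stats::rnorm(n)
      n_sig <- round(spec$signature_fraction * m)
      signal_genes <- sort(sample.int(m, n_sig))
      loadings <- stats::rnorm(n_sig, sd = spec$loading_sd)
      values[signal_genes, ] <- values[signal_genes, ] +
        outer(loadings, latent)
      log_hr <- spec$log_hazard_ratio * latent
      # the signature gene most strongly loaded on the meta-gene plays
      # the role PCNA plays for the proliferation program
      if (n_sig > 0)
        anchor_gene <- gene_ids[signal_genes[which.max(abs(loadings))]]
    } else if (spec$structure == "subclasses") {
      subclass <- sample.int(spec$n_subclasses, n, replace = TRUE,
                             prob = spec$mixing)
      n_de <- round(spec$de_fraction * m)
      signal_genes <- sort(sample.int(m, n_de))
      # per-gene random high/low class pattern, never all-equal, so the
      # class signal is diffuse: no gene is a lone perfect marker
      k <- spec$n_subclasses
      if (n_de > 0 && k > 1) {
        pat <- matrix(stats::rbinom(n_de * k, 1L, 0.5), n_de, k)
        redo <- rowSums(pat) %in% c(0L, k)
        while (any(redo)) {
          pat[redo, ] <- stats::rbinom(sum(redo) * k, 1L, 0.5)
          redo <- rowSums(pat) %in% c(0L, k)
        }
        shift <- spec$de_effect * spec$noise_sd
        values[signal_genes, ] <- values[signal_genes, ] +
          shift * pat[, subclass, drop = FALSE]
      }
      log_hr <- spec$per_class_log_hazard[subclass]
    }

    hazard <- spec$baseline_hazard * exp(log_hr)
    t_event <- stats::rexp(n, rate = hazard)
    t_cens <- stats::rexp(n, rate = spec$censoring_rate)
    obs_time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    structure(list(
      expression = expression_matrix(values, gene_ids, sample_ids,
                                     log_transformed = TRUE),
      survival = survival_table(sample_ids, obs_time, event),
      truth = list(latent = latent, subclass = subclass,
                   signal_genes = signal_genes, loadings = loadings,
                   anchor_gene = anchor_gene),
      spec = spec), class = "SyntheticCohort")
  })
}

#' Generate survival-only data under pure randomness
#'
#' Exponential event times with independent exponential censoring and no
#' expression at all; the substrate for calibrating the empirical null of
#' random group assignments. The expected event fraction is
#' `baseline_hazard / (baseline_hazard + censoring_rate)` (competing
#' exponentials).
#'
#' @param n_samples number of samples (>= 20).
#' @param baseline_hazard exponential event rate.
#' @param censoring_rate exponential censoring rate.
#' @param seed integer RNG seed.
#' @return a [survival_table()].
#' @export
generate_null_assignment_cohort <- function(n_samples = 300L,
                                            baseline_hazard = 0.01,
                                            censoring_rate = 0.003,
                                            seed = 1L) {
  if (!is_count(n_samples, min = 20L))
    stop_field("n_samples", "must be an integer >= 20")
  if (!is_scalar_num(baseline_hazard) || baseline_hazard <= 0)
    stop_field("baseline_hazard", "must be > 0")
  if (!is_scalar_num(censoring_rate) || censoring_rate <= 0)
    stop_field("censoring_rate", "must be > 0")
  with_seed(seed, {
    t_event <- stats::rexp(n_samples, rate = baseline_hazard)
    t_cens <- stats::rexp(n_samples, rate = censoring_rate)
    survival_table(sprintf("s%04d", seq_len(n_samples)),
                   pmin(t_event, t_cens),
                   as.integer(t_event <= t_cens))
  })
}
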