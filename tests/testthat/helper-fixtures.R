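# Shared fixtures: small, fast generator configurations and a null
# configuration with every systematic effect switched off.

small_config <- function(n = 120, ...) {
  generator_config(n_per_group = c(control = n, PD = n, RBD = n),
                   n_per_decade = 50, ...)
}

# All effects zero: no group deficits, no confound gradients, no device
# offsets, no missingness. The latent loading structure is kept unless
# zero_loadings = TRUE (independent measures).
null_config <- function(n = 100, zero_loadings = FALSE, ...) {
  opts <- list(
    n_per_group = c(control = n, PD = n, RBD = n),
    n_per_decade = 50,
    group_accuracy = c(PD = 0, RBD = 0),
    group_latency = c(PD = 0, RBD = 0),
    age_gradients = c(executive = 0, visuospatial_attention = 0,
                      short_term_memory = 0, word_knowledge = 0,
                      motor_rt = 0),
    education_offsets = c(`none` = 0, `<5y` = 0, `5-10y` = 0, `>10y` = 0),
    ...)
  cfg <- do.call(generator_config, opts)
  cfg$sex_effects[] <- 0
  cfg$device_offsets[] <- 0
  cfg$missingness[] <- 0
  cfg$rbd_subgroup$latency_gap <- 0
  cfg$rbd_subgroup$accuracy_gap <- 0
  if (zero_loadings) {
    cfg$loadings[] <- 0
    cfg$psi <- rep(1, nrow(cfg$loadings))
  }
  cfg
}

# Wrap a plain score matrix as the adjusted-matrix container the
# downstream stages consume.
make_adjusted <- function(scores, group,
                          participant_id = sprintf("P%04d", seq_len(nrow(scores)))) {
  structure(list(
    scores = scores,
    participants = tibble::tibble(
      participant_id = participant_id,
      group = factor(group, levels = c("control", "PD", "RBD"))),
    models = list(),
    r_squared = tibble::tibble(measure_id = character(),
                               r_squared = numeric()),
    covariates = character(), fit_population = "pooled", offset = 3 / 8,
    catalog = task_catalog()), class = "cb_adjusted")
}

make_composite <- function(score, group,
                           participant_id = sprintf("P%04d", seq_along(score))) {
  out <- tibble::tibble(participant_id = participant_id,
                        group = factor(group,
                                       levels = c("control", "PD", "RBD")),
                        score = score)
  class(out) <- c("cb_composites", class(out))
  out
}

quiet <- function(expr) suppressMessages(expr)

# all permutations of 1..n as rows
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
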