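#' Build a full-factorial field-trial design
#'
#' Emulates a multi-environment randomized block trial: organs sampled from
#' each plot at two developmental stages, for every genotype x trial x
#' replicate combination. Trials are grouped into growing conditions: the
#' first `n_ws_trials` trials are water-stressed (`WS`), the remainder
#' high-yielding (`HY`), mirroring the common practice of pooling rainfed and
#' irrigated/favourable sites. The default design (3 organs x 2 stages x 5
#' genotypes x 4 trials x 3 replicates) has 60 plots per organ-stage cell and
#' 360 organ samples in total.
#'
#' @param n_genotypes,n_trials,n_replicates Positive integers.
#' @param organs,stages Character vectors of organ and stage labels.
#' @param n_ws_trials Number of leading trials assigned to the `WS` condition
#'   (default: half, rounded up).
#' @return A tibble with columns `sample_id`, `organ`, `stage`, `condition`,
#'   `genotype`, `trial`, `replicate`, in deterministic
#'   (organ, stage, trial, genotype, replicate) order.
#' @examples
#' d <- build_design()
#' nrow(d)                      # 360
#' table(d$organ, d$stage)      # 60 per cell
#' @export
build_design <- function(n_genotypes = 5, n_trials = 4, n_replicates = 3,
                         organs = c("flag_leaf", "glume", "lemma"),
                         stages = c("anthesis", "grain_filling"),
                         n_ws_trials = ceiling(n_trials / 2)) {
  if (n_genotypes < 1 || n_trials < 1 || n_replicates < 1) {
    abort("All design counts must be >= 1.")
  }
  if (length(organs) < 1 || length(stages) < 1) {
    abort("At least one organ and one stage are required.")
  }
  if (anyDuplicated(organs) || anyDuplicated(stages)) {
    abort("Organ and stage labels must be unique.")
  }
  if (n_ws_trials < 0 || n_ws_trials > n_trials) {
    abort("`n_ws_trials` must lie in [0, n_trials].")
  }
  genotypes <- sprintf("geno%02d", seq_len(n_genotypes))
  trials <- sprintf("trial%02d", seq_len(n_trials))
  d <- tidyr::expand_grid(
    organ = organs, stage = stages, trial = trials,
    genotype = genotypes, replicate = seq_len(n_replicates)
  )
  d$condition <- ifelse(match(d$trial, trials) <= n_ws_trials, "WS", "HY")
  d$sample_id <- sprintf("%s.%s.%s.%s.r%d",
                         d$organ, d$stage, d$trial, d$genotype, d$replicate)
  dplyr::select(d, "sample_id", "organ", "stage", "condition",
                "genotype", "trial", "replicate")
}
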