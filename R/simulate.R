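#' Default cell-line panel for simulation
#'
#' The eight-line MCF-7 metallothionein construct panel: the parental line,
#' a blank-vector control, wild-type MT3 (both domains), MT3 with the
#' C-terminal domain mutated (N-terminal only), MT3 with the N-terminal
#' domain mutated (C-terminal only), wild-type MT1E (neither domain), and
#' MT1E carrying the MT3 C- or N-terminal domain. Three replicate arrays per
#' line.
#'
#' @return A tibble with columns `name`, `has_ct`, `has_nt`, `is_reference`,
#'   `n_replicates`.
#' @export
default_lines <- function() {
  tibble(
    name = c("parent", "blank_vector", "MT3", "MT3dCT", "MT3dNT",
             "MT1E", "MT1E-CT", "MT1E-NT"),
    has_ct = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    has_nt = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE),
    is_reference = c(TRUE, rep(FALSE, 7)),
    n_replicates = 3L
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic expression study. Intensities are log-normal:
#' log intensity = per-probe baseline + log(true fold factor) + noise. A
#' single planted block of co-regulated probes is up-regulated by
#' `ct_effect` in lines carrying only the C-terminal domain and
#' down-regulated by `nt_effect` in every line carrying the N-terminal
#' domain (N-terminal suppression is dominant over C-terminal induction).
#'
#' @param n_probes Number of probes on the panel.
#' @param lines Tibble as returned by [default_lines()].
#' @param planted_block_size Number of co-regulated probes in the planted
#'   block (a GAGE-like multicopy family).
#' @param ct_effect Multiplicative up-regulation (> 1) for CT-only lines.
#' @param nt_effect Multiplicative down-regulation (in (0, 1)) for NT lines.
#' @param baseline_log_mean,baseline_log_sd Natural-log-scale mean and sd of
#'   per-probe baseline intensity.
#' @param noise_log_sd Per-array log-scale noise sd (>= 0; 0 gives the
#'   noiseless limit).
#' @param seed Integer seed for the single global stream.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_probes = 2000L,
                       lines = default_lines(),
                       planted_block_size = 16L,
                       ct_effect = 4,
                       nt_effect = 0.25,
                       baseline_log_mean = 5.5,
                       baseline_log_sd = 1,
                       noise_log_sd = 0.3,
                       seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes), lines = as_tibble(lines),
              planted_block_size = as.integer(planted_block_size),
              ct_effect = ct_effect, nt_effect = nt_effect,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              noise_log_sd = noise_log_sd, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  l <- cfg$lines
  need <- c("name", "has_ct", "has_nt", "is_reference", "n_replicates")
  if (!all(need %in% names(l))) {
    abort("`lines` must have columns name, has_ct, has_nt, is_reference, n_replicates")
  }
  if (!any(l$is_reference)) abort("config error: no reference line defined")
  if (any(l$is_reference & (l$has_ct | l$has_nt))) {
    abort("config error: the reference line must carry no planted effects")
  }
  if (anyDuplicated(l$name)) abort("config error: duplicate line names")
  if (any(l$n_replicates < 1L)) abort("config error: n_replicates must be >= 1")
  if (cfg$ct_effect <= 1) abort("config error: ct_effect must be > 1")
  if (cfg$nt_effect <= 0 || cfg$nt_effect >= 1) {
    abort("config error: nt_effect must be in (0, 1)")
  }
  if (cfg$planted_block_size > cfg$n_probes || cfg$planted_block_size < 0) {
    abort("config error: planted_block_size must be in [0, n_probes]")
  }
  if (cfg$baseline_log_sd <= 0 || cfg$noise_log_sd < 0) {
    abort("config error: baseline_log_sd must be > 0 and noise_log_sd >= 0")
  }
  cfg
}

# True multiplicative fold factor of the planted block for one line.
planted_fold <- function(has_ct, has_nt, ct_effect, nt_effect) {
  ifelse(has_nt, nt_effect, ifelse(has_ct, ct_effect, 1))
}

#' Simulate an expression study
#'
#' Draws a probes-by-arrays intensity matrix under `config`, together with
#' its sample sheet and the ground truth of planted effects. Identical seeds
#' give identical output.
#'
#' @param config A [sim_config()].
#' @return A list with elements `expression` (tibble, `probe_id` + one column
#'   per array), `samples` (sample sheet tibble) and `truth` (tibble
#'   `cell_line`, `probe_id`, `fold` for every line with a non-unit planted
#'   factor, plus attribute `block` holding the planted probe ids).
#' @export
simulate_expression <- function(config = sim_config()) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  probe_ids <- sprintf("probe%04d", seq_len(cfg$n_probes))
  block <- sort(sample(cfg$n_probes, cfg$planted_block_size))
  baseline <- rnorm(cfg$n_probes, cfg$baseline_log_mean, cfg$baseline_log_sd)

  samples <- cfg$lines %>%
    mutate(replicate = purrr::map(.data$n_replicates, function(k) {
      rep_labels <- c(letters, paste0(rep(letters, each = 26),
                                      rep(letters, times = 26)))
      rep_labels[seq_len(k)]
    })) %>%
    tidyr::unnest("replicate") %>%
    mutate(array_id = paste0(.data$name, "_", .data$replicate)) %>%
    select("array_id", cell_line = "name", "replicate", "is_reference",
           "has_ct", "has_nt")

  folds <- planted_fold(samples$has_ct, samples$has_nt,
                        cfg$ct_effect, cfg$nt_effect)
  expression <- tibble(probe_id = probe_ids)
  for (i in seq_len(nrow(samples))) {
    logfc <- numeric(cfg$n_probes)
    logfc[block] <- log(folds[i])
    noise <- if (cfg$noise_log_sd > 0) {
      rnorm(cfg$n_probes, 0, cfg$noise_log_sd)
    } else 0
    expression[[samples$array_id[i]]] <- exp(baseline + logfc + noise)
  }

  line_folds <- planted_fold(cfg$lines$has_ct, cfg$lines$has_nt,
                             cfg$ct_effect, cfg$nt_effect)
  truth <- tibble(cell_line = rep(cfg$lines$name, each = length(block)),
                  probe_id = rep(probe_ids[block], nrow(cfg$lines)),
                  fold = rep(line_folds, each = length(block))) %>%
    filter(.data$fold != 1)
  attr(truth, "block") <- probe_ids[block]

  list(expression = validate_expression_matrix(expression),
       samples = validate_sample_sheet(samples),
       truth = truth)
}

#' Simulate an MTT growth curve
#'
#' Absorbance follows lag, then exponential growth doubling every `true_td`
#' hours, then a plateau, with additive Gaussian reading noise. Triplicate
#' wells per time point by default.
#'
#' @param true_td True doubling time in hours (> 0).
#' @param t_points Strictly increasing time points in hours.
#' @param lag Lag before exponential growth starts, hours.
#' @param plateau_level Absorbance ceiling (Inf for none).
#' @param noise_sd Additive absorbance noise sd (>= 0).
#' @param n_wells Replicate wells per time point.
#' @param a0 Absorbance at the end of the lag phase.
#' @param seed Optional integer seed.
#' @return A tibble `time_h`, `well`, `absorbance` with attribute `true_td`.
#' @export
simulate_growth <- function(true_td, t_points, lag = 0, plateau_level = Inf,
                            noise_sd = 0, n_wells = 3L, a0 = 0.05,
                            seed = NULL) {
  stopifnot_scalar_number(true_td, "true_td", positive = TRUE)
  if (any(diff(t_points) <= 0)) abort("`t_points` must be strictly increasing")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  mu <- pmin(a0 * 2^(pmax(t_points - lag, 0) / true_td), plateau_level)
  curve <- tidyr::expand_grid(time_h = t_points, well = seq_len(n_wells)) %>%
    mutate(absorbance = rep(mu, each = n_wells) +
             if (noise_sd > 0) rnorm(dplyr::n(), 0, noise_sd) else 0)
  attr(curve, "true_td") <- true_td
  curve
}

#' Simulate dome-count and transepithelial-resistance tables
#'
#' Per-field dome counts are Poisson with rate `dome_rate`; raw TER readings
#' are Gaussian around `blank_ohm + ter_mean` so that blank subtraction
#' recovers `ter_mean`.
#'
#' @param dome_rate Poisson rate, domes per 100x field (>= 0).
#' @param n_fields Fields of view scored per flask (21 per T-25 flask).
#' @param n_flasks Replicate flasks.
#' @param ter_mean,ter_sd Mean and sd of blank-subtracted resistance (Ohm).
#' @param n_days Number of post-confluence measurement days (day 5 onward).
#' @param n_filters Replicate filters per day.
#' @param n_readings Raw readings per filter (two sets of four).
#' @param blank_ohm Bare-filter resistance subtracted from each reading.
#' @param area_cm2 Membrane area used to scale resistances.
#' @param seed Optional integer seed.
#' @return A list of tibbles `domes` (`flask`, `field_index`, `count`) and
#'   `ter` (`filter`, `day`, `reading_index`, `resistance_ohm`, `blank_ohm`,
#'   `area_cm2`), plus `truth`.
#' @export
simulate_phenotype <- function(dome_rate, n_fields = 21L, n_flasks = 3L,
                               ter_mean = 40, ter_sd = 8, n_days = 3L,
                               n_filters = 3L, n_readings = 8L,
                               blank_ohm = 100, area_cm2 = 1,
                               seed = NULL) {
  if (dome_rate < 0) abort("`dome_rate` must be >= 0")
  if (n_fields < 1L || n_flasks < 1L) abort("counts must be positive")
  if (!is.null(seed)) set.seed(seed)
  domes <- tidyr::expand_grid(flask = seq_len(n_flasks),
                              field_index = seq_len(n_fields)) %>%
    mutate(count = rpois(dplyr::n(), dome_rate))
  ter <- tidyr::expand_grid(filter = seq_len(n_filters),
                            day = 4L + seq_len(n_days),
                            reading_index = seq_len(n_readings)) %>%
    mutate(resistance_ohm = blank_ohm + rnorm(dplyr::n(), ter_mean, ter_sd),
           blank_ohm = blank_ohm, area_cm2 = area_cm2)
  list(domes = domes, ter = ter,
       truth = list(dome_rate = dome_rate, ter_mean = ter_mean))
}
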