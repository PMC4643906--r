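# Synthetic radioenzymatic-assay generator.
#
# Emulates the statistical structure of radiolabelled-substrate hydrolysis
# assays in tissue homogenates: a small grid of substrate concentrations
# (default 8 values spanning 0.5-4 uM), a few inhibitor levels, 3-4
# replicates, and noise that is predominantly proportional to the signal
# (constant CV), with an optional additive floor for low-velocity wells.
# Every table is produced from an integer seed and is bit-reproducible.

#' Albumin model implied by the assay substrate mix
#'
#' In the emulated assay the substrate is delivered complexed with fatty
#' acid-free bovine serum albumin at a fixed substrate:albumin molar ratio
#' of about 1:4.5, so the albumin binding capacity scales with the added
#' substrate concentration.
#'
#' @param substrate_uM Added substrate concentration (uM), default 0.5.
#' @param ratio Albumin-to-substrate molar ratio, default 4.5.
#' @param kd Site dissociation constant for the inhibitor (uM), default 1.
#' @return An [albumin_model()] with `capacity = ratio * substrate_uM`.
#' @export
assay_albumin_model <- function(substrate_uM = 0.5, ratio = 4.5, kd = 1) {
  albumin_model(capacity = ratio * substrate_uM, kd = kd)
}

#' Simulation configuration
#'
#' Bundles everything needed to generate a synthetic velocity or
#' concentration-response table. Defaults mirror a typical kinetic design:
#' 8 substrate concentrations evenly spanning 0.5-4 uM, 4 inhibitor levels
#' bracketing the Ki, 3 replicates, and 5% multiplicative noise.
#'
#' @param seed Integer seed; identical configurations give identical tables.
#' @param substrate_grid Substrate concentrations (uM).
#' @param inhibitor_grid Primary-inhibitor concentrations (uM).
#' @param inhibitor2_grid Second-inhibitor concentrations (uM) for
#'   two-inhibitor designs, or `NULL`.
#' @param n_replicates Replicates per condition (default 3).
#' @param noise_cv Fractional coefficient of variation of the
#'   multiplicative Gaussian noise (default 0.05).
#' @param additive_sd Standard deviation of an optional additive noise
#'   floor, in velocity units (default 0).
#' @param model Generating model: a list with `type` in `"mm"`, `"mixed"`,
#'   `"competitive"`, `"two_inhibitor_exclusive"`,
#'   `"two_inhibitor_synergistic"` and the corresponding parameters
#'   (`Km`, `Vmax`, plus `Ki`/`alpha`, or `K1`/`K2`/`beta`).
#' @param albumin Optional [albumin_model()]; when present the inhibitor
#'   concentration entering the velocity model is the free concentration
#'   after albumin sequestration.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              substrate_grid = seq(0.5, 4, length.out = 8),
                              inhibitor_grid = c(0, 0.5, 1, 2),
                              inhibitor2_grid = NULL,
                              n_replicates = 3L,
                              noise_cv = 0.05,
                              additive_sd = 0,
                              model = list(type = "mixed", Km = 1, Vmax = 10,
                                           Ki = 0.8, alpha = 3.2),
                              albumin = NULL) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop_inhibkin("'seed' must be an integer", "invalid_parameter")
  if (length(substrate_grid) < 1L || length(inhibitor_grid) < 1L)
    stop_inhibkin("concentration grids must be non-empty", "invalid_parameter")
  if (noise_cv < 0 || additive_sd < 0)
    stop_inhibkin("noise parameters must be >= 0", "invalid_parameter")
  if (!is.list(model) || is.null(model$type))
    stop_inhibkin("'model' must be a list with a 'type' entry", "invalid_parameter")
  types <- c("mm", "mixed", "competitive",
             "two_inhibitor_exclusive", "two_inhibitor_synergistic")
  if (!model$type %in% types)
    stop_inhibkin(paste0("unknown model type '", model$type, "'"),
                  "invalid_parameter")
  if (startsWith(model$type, "two_inhibitor") && is.null(inhibitor2_grid))
    stop_inhibkin("two-inhibitor models need 'inhibitor2_grid'", "invalid_parameter")
  if (!is.null(albumin)) stopifnot(inherits(albumin, "albumin_model"))
  structure(list(seed = seed, substrate_grid = substrate_grid,
                 inhibitor_grid = inhibitor_grid,
                 inhibitor2_grid = inhibitor2_grid,
                 n_replicates = as.integer(n_replicates),
                 noise_cv = noise_cv, additive_sd = additive_sd,
                 model = model, albumin = albumin),
            class = "simulation_config")
}

# Deterministic true velocity for a config's generating model.
model_velocity <- function(model, S, I, I2 = NULL) {
  p <- mm_params(Km = model$Km, Vmax = model$Vmax)
  switch(model$type,
    mm = mm_velocity(S, p),
    mixed = mixed_inhibition_velocity(S, I, p,
              inhibition_params(Ki = model$Ki, alpha = model$alpha)),
    competitive = competitive_velocity(S, I, p, model$Ki),
    two_inhibitor_exclusive =
      model$Vmax * S / (model$Km * (1 + I / model$K1 + I2 / model$K2) + S),
    two_inhibitor_synergistic = {
      beta <- if (is.null(model$beta)) 1 else model$beta
      model$Vmax * S /
        (model$Km * (1 + I / model$K1 + I2 / model$K2 +
                       I * I2 / (beta * model$K1 * model$K2)) + S)
    },
    stop_inhibkin("unknown model type", "invalid_parameter"))
}

#' Simulate a steady-state velocity table
#'
#' Generates observed velocities `v_obs = v_model * (1 + e_m) + e_a` with
#' `e_m ~ N(0, noise_cv)` and `e_a ~ N(0, additive_sd)`, over the full
#' substrate x inhibitor (x second inhibitor) x replicate grid of the
#' configuration. When an albumin model is configured, the inhibitor
#' concentration entering the velocity model is its free concentration.
#' Negative draws are truncated at zero and flagged in the `truncated`
#' column, since a measured hydrolysis cannot be negative.
#'
#' @param config A [simulation_config()].
#' @return A data frame of class `velocity_table` with columns
#'   `substrate_uM`, `inhibitor_uM`, (`inhibitor2_uM`,) `replicate`,
#'   `velocity`, `truncated`, and the generating configuration in
#'   `attr(, "config")`.
#' @examples
#' tab <- simulate_velocity_table(simulation_config(seed = 7))
#' head(tab)
#' @export
simulate_velocity_table <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  two <- !is.null(config$inhibitor2_grid)
  grid <- if (two)
    expand.grid(substrate_uM = config$substrate_grid,
                inhibitor_uM = config$inhibitor_grid,
                inhibitor2_uM = config$inhibitor2_grid,
                replicate = seq_len(config$n_replicates),
                KEEP.OUT.ATTRS = FALSE)
  else
    expand.grid(substrate_uM = config$substrate_grid,
                inhibitor_uM = config$inhibitor_grid,
                replicate = seq_len(config$n_replicates),
                KEEP.OUT.ATTRS = FALSE)
  I_eff <- if (!is.null(config$albumin))
    free_concentration(grid$inhibitor_uM, config$albumin)
  else grid$inhibitor_uM
  v_true <- model_velocity(config$model, grid$substrate_uM, I_eff,
                           if (two) grid$inhibitor2_uM else NULL)
  set.seed(config$seed)
  n <- nrow(grid)
  v_obs <- v_true * (1 + stats::rnorm(n, 0, config$noise_cv))
  if (config$additive_sd > 0)
    v_obs <- v_obs + stats::rnorm(n, 0, config$additive_sd)
  grid$truncated <- v_obs < 0
  grid$velocity <- pmax(v_obs, 0)
  grid <- grid[, c(setdiff(names(grid), c("truncated", "velocity")),
                   "velocity", "truncated")]
  structure(grid, class = c("velocity_table", "data.frame"), config = config)
}

#' Simulate a concentration-response experiment
#'
#' Generates percent-of-control responses from a potency curve (optionally
#' distorted by albumin sequestration of the inhibitor), with
#' multiplicative noise, then normalises so that the zero-inhibitor control
#' wells average exactly 100. A zero-inhibitor level is added to the grid
#' if absent, since the normalisation needs control wells.
#'
#' @param config A [simulation_config()]; only its `seed`,
#'   `inhibitor_grid`, `n_replicates`, `noise_cv` and `albumin` entries are
#'   used.
#' @param potency [potency_params()] of the generating curve (as a function
#'   of the free concentration when albumin is configured).
#' @return Data frame with columns `inhibitor_uM`, `replicate`, `response`,
#'   plus the configuration in `attr(, "config")`.
#' @export
simulate_conc_response <- function(config, potency) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(potency, "potency_params"))
  grid_conc <- sort(unique(c(0, config$inhibitor_grid)))
  grid <- expand.grid(inhibitor_uM = grid_conc,
                      replicate = seq_len(config$n_replicates),
                      KEEP.OUT.ATTRS = FALSE)
  free <- if (!is.null(config$albumin))
    free_concentration(grid$inhibitor_uM, config$albumin)
  else grid$inhibitor_uM
  lg <- ifelse(free > 0, log10(free * 1e-6), -Inf)
  r_true <- four_pl_response(lg, potency)
  set.seed(config$seed)
  r_obs <- r_true * (1 + stats::rnorm(nrow(grid), 0, config$noise_cv))
  ctrl <- mean(r_obs[grid$inhibitor_uM == 0])
  grid$response <- r_obs / ctrl * 100
  structure(grid, class = c("data.frame"), config = config)
}

#' Expected outcome of a dilution reversibility experiment
#'
#' Arithmetic of the preincubate-then-dilute protocol used to distinguish
#' reversible from irreversible inhibition: homogenate is preincubated at a
#' high inhibitor concentration, an aliquot is diluted `fold`-fold, and the
#' residual activity is compared with (a) the undiluted concentration and
#' (b) a matched free concentration equal to `conc / fold` added without
#' preincubation. For a fully reversible inhibitor the diluted arm matches
#' the matched-free arm; for an irreversible one it stays at the
#' preincubation level.
#'
#' @param preinc_concs Preincubation concentrations (uM).
#' @param fold Dilution factor, > 1 (e.g. 20).
#' @param mode `"reversible"` or `"irreversible"`.
#' @param potency [potency_params()] of the equilibrium inhibition curve.
#' @return Data frame with one row per preincubation concentration:
#'   `preinc_uM`, `diluted_uM` (= `preinc_uM / fold`), and the percent-of-
#'   control activities `pct_undiluted`, `pct_diluted`, `pct_matched_free`.
#' @examples
#' pp <- potency_params(pIC50 = 6.13, hill_slope = 1)
#' simulate_dilution_experiment(c(2, 4, 6), 20, "reversible", pp)
#' @export
simulate_dilution_experiment <- function(preinc_concs, fold,
                                         mode = c("reversible", "irreversible"),
                                         potency) {
  mode <- match.arg(mode)
  stopifnot(inherits(potency, "potency_params"))
  if (!is.numeric(fold) || length(fold) != 1L || fold <= 1)
    stop_inhibkin("'fold' must be a single number > 1", "invalid_parameter")
  if (any(preinc_concs <= 0))
    stop_inhibkin("preincubation concentrations must be > 0", "invalid_parameter")
  resp <- function(c_uM) four_pl_response(log10(c_uM * 1e-6), potency)
  diluted <- preinc_concs / fold
  data.frame(
    preinc_uM = preinc_concs,
    diluted_uM = diluted,
    pct_undiluted = resp(preinc_concs),
    pct_diluted = if (mode == "reversible") resp(diluted) else resp(preinc_concs),
    pct_matched_free = resp(diluted)
  )
}
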