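#' Simulate one co-culture OD600 growth curve
#'
#' Integrates the mass-action S/I/R/P co-culture model and maps total cell
#' density to OD600 with additive truncated-Gaussian plate-reader noise. The
#' model is
#' \deqn{dS/dt = r S (1 - N/K) - \delta S P - \mu_{res} S}
#' \deqn{dR/dt = r R (1 - N/K) + \mu_{res} S}
#' \deqn{dI/dt = \delta S P - I/\tau}
#' \deqn{dP/dt = (\beta/\tau) I - \delta N P - \lambda P}
#' with \eqn{N = S + I + R} and \eqn{OD(t) = c \cdot N(t) + \epsilon},
#' \eqn{\epsilon \sim N(0, \sigma^2)} truncated at 0. Lysed cells contribute
#' nothing to OD; infected and resistant cells contribute fully, since optical
#' density cannot distinguish compartments.
#'
#' Integration uses an adaptive stiff-capable solver (`deSolve::lsoda`) with
#' the state clamped at 0 after each output step, so trajectories are never
#' negative even when burst terms make the system stiff.
#'
#' @param params A [coculture_params()] object.
#' @param t_grid Strictly increasing observation times in hours, starting
#'   at 0.
#' @param seed Integer seed for the observation noise; `NULL` uses the
#'   current RNG state. With `noise_sd = 0` the output is deterministic.
#' @param well_id,isolate_id,phage_id,moi,replicate Metadata attached to the
#'   returned curve; `phage_id = NA` marks a phage-free control.
#' @param keep_states If `TRUE`, the S/I/R/P trajectories are kept as extra
#'   columns.
#'
#' @return A tibble with one row per grid point: `well_id`, `isolate_id`,
#'   `phage_id`, `moi`, `replicate`, `time_h`, `od600` (plus `S`, `I`, `R`,
#'   `P` when `keep_states = TRUE`).
#' @examples
#' p <- coculture_params(P0 = 1e6, noise_sd = 0)
#' curve <- simulate_growth_curve(p, t_grid = 0:24)
#' head(curve)
#' @seealso [simulate_killing_assay()] for a full multi-well assay.
#' @export
simulate_growth_curve <- function(params, t_grid = 0:24, seed = NULL,
                                  well_id = "A1", isolate_id = "isolate_1",
                                  phage_id = NA_character_, moi = NA_real_,
                                  replicate = 1L, keep_states = FALSE) {
  stopifnot(inherits(params, "coculture_params"))
  validate_coculture_params(params)
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0)) {
    abort("t_grid must be strictly increasing with at least 2 points")
  }
  if (t_grid[1] != 0) abort("t_grid must start at 0")

  states <- integrate_coculture(params, t_grid)
  n_total <- states[, "S"] + states[, "I"] + states[, "R"]
  od <- params$od_per_cell * n_total
  if (params$noise_sd > 0) {
    eps <- if (is.null(seed)) {
      rnorm(length(od), 0, params$noise_sd)
    } else {
      withr::with_seed(as.integer(seed) %% 2147483647L,
                       rnorm(length(od), 0, params$noise_sd))
    }
    od <- pmax(od + eps, 0)
  }

  out <- tibble::tibble(
    well_id = well_id,
    isolate_id = isolate_id,
    phage_id = phage_id,
    moi = moi,
    replicate = as.integer(replicate),
    time_h = as.numeric(t_grid),
    od600 = od
  )
  if (keep_states) {
    out$S <- states[, "S"]
    out$I <- states[, "I"]
    out$R <- states[, "R"]
    out$P <- states[, "P"]
  }
  out
}

# lsoda over each inter-observation interval, clamping the state at 0 after
# every accepted output step.
integrate_coculture <- function(params, t_grid) {
  rhs <- function(t, y, p) {
    y <- pmax(y, 0)
    S <- y[1]; I <- y[2]; R <- y[3]; P <- y[4]
    N <- S + I + R
    dS <- p$r * S * (1 - N / p$K) - p$delta * S * P - p$mu_res * S
    dR <- p$r * R * (1 - N / p$K) + p$mu_res * S
    dI <- p$delta * S * P - I / p$tau
    dP <- (p$beta / p$tau) * I - p$delta * N * P - p$lam * P
    list(c(dS, dI, dR, dP))
  }
  state <- c(S = params$S0, I = 0, R = 0, P = params$P0)
  out <- matrix(NA_real_, nrow = length(t_grid), ncol = 4,
                dimnames = list(NULL, c("S", "I", "R", "P")))
  out[1, ] <- state
  for (i in seq_len(length(t_grid) - 1)) {
    sol <- deSolve::lsoda(
      y = state, times = c(t_grid[i], t_grid[i + 1]), func = rhs,
      parms = params, rtol = 1e-8, atol = 1e-4
    )
    state <- pmax(sol[nrow(sol), c("S", "I", "R", "P")], 0)
    out[i + 1, ] <- state
  }
  out
}

#' Simulate a complete planktonic killing assay
#'
#' Builds a phage-free control plus one treatment condition per requested MOI
#' (multiplicity of infection), each with `n_replicates` wells on a shared
#' time grid. The initial free-phage density of each treatment is
#' `moi * S0`. Each well draws its observation noise from an independent,
#' reproducible substream of the global `seed`.
#'
#' @param params A [coculture_params()] object; its `P0` is ignored (set per
#'   condition).
#' @param mois Numeric vector of input MOIs to simulate.
#' @param n_replicates Wells per condition.
#' @param t_grid Observation times in hours.
#' @param seed Integer seed governing all wells.
#' @param isolate_id,phage_id Metadata for the simulated wells.
#'
#' @return A list of class `simulated_assay` with elements `curves` (long
#'   tibble, all wells) and `truth` (the parameters and per-condition P0
#'   used).
#' @examples
#' assay <- simulate_killing_assay(coculture_params(), mois = c(1, 10),
#'                                 n_replicates = 2, seed = 1)
#' dplyr::count(assay$curves, phage_id, moi)
#' @export
simulate_killing_assay <- function(params = coculture_params(),
                                   mois = c(1, 10), n_replicates = 6,
                                   t_grid = 0:24, seed = 1L,
                                   isolate_id = "isolate_1",
                                   phage_id = "phage_1") {
  stopifnot(inherits(params, "coculture_params"))
  if (n_replicates < 1) abort("n_replicates must be >= 1")

  conditions <- tibble::tibble(
    phage = c(NA_character_, rep(phage_id, length(mois))),
    moi = c(NA_real_, mois),
    P0 = c(0, mois * params$S0)
  )
  k <- 0L
  curves <- purrr::pmap(conditions, function(phage, moi, P0) {
    purrr::map(seq_len(n_replicates), function(rep_i) {
      k <<- k + 1L
      p <- params
      p$P0 <- P0
      well <- sprintf("W%02d", k)
      simulate_growth_curve(
        p, t_grid = t_grid, seed = substream_seed(seed, k),
        well_id = well, isolate_id = isolate_id, phage_id = phage,
        moi = moi, replicate = rep_i
      )
    })
  })
  curves <- dplyr::bind_rows(purrr::flatten(curves))
  structure(
    list(curves = curves,
         truth = list(params = params, conditions = conditions, seed = seed)),
    class = "simulated_assay"
  )
}

#' @export
print.simulated_assay <- function(x, ...) {
  n_well <- dplyr::n_distinct(x$curves$well_id)
  cat(sprintf("<simulated_assay> %d wells x %d time points\n",
              n_well, nrow(x$curves) / n_well))
  print(x$truth$conditions)
  invisible(x)
}

#' Simulate a decimal dilution-series plate-count sheet
#'
#' Draws Poisson plate counts for a 10-fold dilution series of a sample with
#' known true concentration: each plate count has mean
#' `true_conc * 10^exponent * plated_volume`.
#'
#' @param true_conc True concentration of the undiluted sample (CFU or PFU
#'   per mL).
#' @param dilution_exponents Integer dilution exponents, all `<= 0` (e.g.
#'   `-2:-6` for the 10^-2 .. 10^-6 steps of a decimal ladder).
#' @param plated_volume Volume plated per plate, in mL.
#' @param n_plates_per_dilution Plates per dilution level.
#' @param seed Integer seed; fixed seed gives identical counts.
#' @param sample_id,analyte Metadata columns for the returned sheet
#'   (`analyte` is `"CFU"` or `"PFU"`).
#'
#' @return A tibble in count-sheet layout: `sample_id`, `analyte`,
#'   `dilution_exponent`, `plated_volume_ml`, `count`.
#' @examples
#' simulate_dilution_series(1e6, -2:-6, seed = 1)
#' @export
simulate_dilution_series <- function(true_conc,
                                     dilution_exponents = -2:-6,
                                     plated_volume = 0.1,
                                     n_plates_per_dilution = 2,
                                     seed = 1L,
                                     sample_id = "sample_1",
                                     analyte = c("CFU", "PFU")) {
  analyte <- match.arg(analyte)
  if (true_conc < 0) abort("true_conc must be >= 0")
  if (plated_volume <= 0) abort("plated_volume must be > 0")
  if (any(dilution_exponents > 0)) abort("dilution exponents must be <= 0")
  if (n_plates_per_dilution < 1) abort("n_plates_per_dilution must be >= 1")

  exps <- rep(as.integer(dilution_exponents), each = n_plates_per_dilution)
  lambda <- true_conc * 10^exps * plated_volume
  counts <- withr::with_seed(as.integer(seed) %% 2147483647L,
                             rpois(length(lambda), lambda))
  tibble::tibble(
    sample_id = sample_id,
    analyte = analyte,
    dilution_exponent = exps,
    plated_volume_ml = plated_volume,
    count = as.integer(counts)
  )
}

#' Simulate spot/plaque host-range records from a true EOP matrix
#'
#' Generates triplicate (configurable) plaque-count records for every
#' phage x isolate cell of a true efficiency-of-plating matrix. `NA` cells
#' produce `"none"` outcomes (no infection), cells holding the sentinel `-1`
#' produce `"opaque"` outcomes (turbid lysis without countable plaques), and
#' numeric cells produce Poisson plaque counts with mean
#' `ref_titer * eop * 10^exponent * plated_volume`. The dilution exponent is
#' chosen per cell so the expected count is near `target_count`, as a
#' laboratory would pick the countable dilution.
#'
#' @param true_eop Numeric matrix (phages in rows, isolates in columns) with
#'   dimnames; `NA` = no infection, `-1` = opaque-only.
#' @param ref_titer Reference titer of each phage on its original host
#'   (PFU/mL); scalar or one value per phage row.
#' @param plated_volume Spotted volume in mL.
#' @param n_replicates Replicates per cell.
#' @param target_count Expected plaque count the chosen dilution aims for.
#' @param seed Integer seed.
#'
#' @return A tibble of spot records: `phage_id`, `isolate_id`, `replicate`,
#'   `outcome` (`"count"`, `"opaque"`, `"none"`), `plaque_count`,
#'   `dilution_exponent`, `plated_volume_ml`.
#' @examples
#' truth <- matrix(c(1, NA, -1, 0.05), 2, 2,
#'                 dimnames = list(c("p1", "p2"), c("i1", "i2")))
#' simulate_host_range(truth, ref_titer = 1e9, seed = 1)
#' @export
simulate_host_range <- function(true_eop, ref_titer, plated_volume = 0.1,
                                n_replicates = 3, target_count = 30,
                                seed = 1L) {
  if (!is.matrix(true_eop)) abort("true_eop must be a matrix")
  if (is.null(rownames(true_eop)) || is.null(colnames(true_eop))) {
    rownames(true_eop) <- rownames(true_eop) %||% paste0("phage_", seq_len(nrow(true_eop)))
    colnames(true_eop) <- colnames(true_eop) %||% paste0("isolate_", seq_len(ncol(true_eop)))
  }
  ref_titer <- rep_len(ref_titer, nrow(true_eop))
  if (any(ref_titer <= 0)) abort("ref_titer must be > 0 for every phage")
  bad <- !is.na(true_eop) & true_eop < 0 & true_eop != -1
  if (any(bad)) abort("negative EOP values other than the -1 opaque sentinel")

  cells <- tidyr::expand_grid(
    phage_id = rownames(true_eop),
    isolate_id = colnames(true_eop)
  )
  k <- 0L
  recs <- purrr::pmap(cells, function(phage_id, isolate_id) {
    k <<- k + 1L
    eop <- true_eop[phage_id, isolate_id]
    ref <- ref_titer[match(phage_id, rownames(true_eop))]
    if (is.na(eop)) {
      outcome <- "none"; counts <- NA_integer_; e <- NA_integer_
    } else if (eop == -1) {
      outcome <- "opaque"; counts <- NA_integer_; e <- NA_integer_
    } else {
      full <- ref * eop * plated_volume
      e <- as.integer(min(0, round(log10(target_count / full))))
      lambda <- full * 10^e
      counts <- withr::with_seed(
        as.integer(substream_seed(seed, k)),
        rpois(n_replicates, lambda)
      )
      outcome <- "count"
    }
    plaque_count <- if (outcome == "count") as.integer(counts) else
      rep(NA_integer_, n_replicates)
    tibble::tibble(
      phage_id = phage_id, isolate_id = isolate_id,
      replicate = seq_len(n_replicates),
      outcome = outcome,
      plaque_count = plaque_count,
      dilution_exponent = e,
      plated_volume_ml = plated_volume
    )
  })
  dplyr::bind_rows(recs)
}

#' Default synthetic host-range truth matrix
#'
#' A 13-phage x 37-isolate efficiency-of-plating truth matrix shaped like a
#' typical streptococcal phage panel: the two broadest phages infect 30 and
#' 29 isolates, the rest fewer; non-susceptible cells are `NA`, a fraction of
#' positives are opaque-only (`-1`), and numeric EOPs sit in the interiors of
#' the grading bins (0.03, 0.3, 3, 30).
#'
#' @param n_phages,n_isolates Matrix dimensions.
#' @param n_susceptible Integer vector (recycled to `n_phages`) of
#'   susceptible-isolate counts per phage; the default places 30 and 29 in
#'   the first two rows.
#' @param seed Integer seed for the arrangement of cells.
#' @return A numeric matrix with dimnames, usable as `true_eop` in
#'   [simulate_host_range()].
#' @examples
#' truth <- default_host_range_truth(seed = 1)
#' rowSums(!is.na(truth))
#' @export
default_host_range_truth <- function(n_phages = 13, n_isolates = 37,
                                     n_susceptible = c(30, 29, 26, 24, 22,
                                                       20, 18, 16, 14, 12,
                                                       10, 8, 6),
                                     seed = 1L) {
  n_susceptible <- rep_len(n_susceptible, n_phages)
  if (any(n_susceptible > n_isolates)) abort("n_susceptible exceeds n_isolates")
  eop_bins <- c(0.03, 0.3, 3, 30)   # interiors of low/moderate/high/ultimate
  withr::with_seed(as.integer(seed) %% 2147483647L, {
    m <- matrix(NA_real_, n_phages, n_isolates,
                dimnames = list(paste0("phage_", seq_len(n_phages)),
                                paste0("isolate_", sprintf("%02d", seq_len(n_isolates)))))
    for (i in seq_len(n_phages)) {
      hit <- sample.int(n_isolates, n_susceptible[i])
      vals <- sample(c(eop_bins, -1), length(hit), replace = TRUE,
                     prob = c(0.25, 0.35, 0.15, 0.05, 0.20))
      m[i, hit] <- vals
    }
    m
  })
}

#' Simulate explant endpoint concentrations
#'
#' Draws log-normally distributed endpoint concentrations,
#' `10^Normal(mean_log10, sd_log10)`, emulating the dispersion of explant
#' CFU/mL and PFU/mL endpoints.
#'
#' @param mean_log10 Mean of the log10 concentration.
#' @param sd_log10 Standard deviation of the log10 concentration (`>= 0`).
#' @param n Number of values (`>= 1`).
#' @param seed Integer seed.
#' @return Numeric vector of `n` positive concentrations (per mL).
#' @examples
#' simulate_explant_endpoint(7, 0.4, n = 5, seed = 1)
#' @export
simulate_explant_endpoint <- function(mean_log10, sd_log10 = 0.4, n = 8,
                                      seed = 1L) {
  if (n < 1) abort("n must be >= 1")
  if (sd_log10 < 0) abort("sd_log10 must be >= 0")
  withr::with_seed(as.integer(seed) %% 2147483647L,
                   10^rnorm(n, mean_log10, sd_log10))
}
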