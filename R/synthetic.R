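#' Pulse-train series container
#'
#' Per-train, per-pulse 1D scattering profiles with light/dark flags and the
#' intra-train delay grid. Synthetic series carry an embedded ground-truth
#' record (rates, yield, basis spectra, corrupted-train ids).
#'
#' @param profiles List of q x n_pulses matrices, one per train.
#' @param q A [q_grid()] or increasing numeric vector.
#' @param time_us Per-pulse delay grid in µs.
#' @param light_flag Logical vector, one per train; must strictly alternate
#'   (every other train is laser-excited).
#' @param truth Ground-truth list for synthetic data, or \code{NULL}.
#' @param check_alternating Require strictly alternating flags (the
#'   acquisition pattern); disabled for filtered subsets.
#' @return Object of class \code{train_series}.
#' @export
train_series <- function(profiles, q, time_us, light_flag, truth = NULL,
                         check_alternating = TRUE) {
  q <- as_q_grid(q)
  if (!is.list(profiles) || length(profiles) == 0) stop("profiles must be a non-empty list")
  nq <- length(q$values); np <- length(time_us)
  ok <- vapply(profiles, function(p) all(dim(p) == c(nq, np)), logical(1))
  if (!all(ok)) stop("every train must be a q x n_pulses matrix matching the grids")
  if (length(light_flag) != length(profiles)) stop("one light flag per train")
  if (check_alternating && length(light_flag) > 1 && any(diff(light_flag) == 0)) {
    stop("light/dark flags must strictly alternate")
  }
  structure(list(profiles = profiles, q = q, time_us = as.numeric(time_us),
                 light_flag = as.logical(light_flag), truth = truth),
            class = "train_series")
}

#' @export
print.train_series <- function(x, ...) {
  cat(sprintf("train series: %d trains (%d light), %d pulses, %d q bins\n",
              length(x$profiles), sum(x$light_flag), length(x$time_us),
              length(x$q$values)))
  invisible(x)
}

#' Configuration of the synthetic pulse-train generator
#'
#' Defaults encode the pulse-train structure of a MHz XFEL pump-probe
#' experiment (175 pulses per train at 564 kHz, alternate trains excited)
#' and a photoactivation yield of 15%. Rates default to a fast first step
#' (within the first 1.77 µs time point) and a slow second step completing
#' within the ~300 µs train span.
#'
#' @param n_train_pairs Number of light/dark train pairs.
#' @param pulses_per_train Pulses per train.
#' @param intra_train_rate Intra-train repetition rate, Hz.
#' @param photons_per_pulse_scale Expected integrated photons per pulse.
#'   The default is sized so that, after averaging the default number of
#'   train pairs, the difference-signal noise floor sits at the 1e-5
#'   (0.001%) level relative to the absolute background.
#' @param yield_c Photoactivation yield (fraction of excited molecules).
#' @param rates Named or plain numeric: k_A (and k_B) in µs^-1.
#' @param jitter_sd Stationary relative sd of the train-level multiplicative
#'   common-mode factor (jet thickness / beam intensity). The factor drifts
#'   slowly across trains (AR(1), adjacent-train correlation 0.9), which is
#'   why adjacent light/dark train subtraction suppresses it.
#' @param corrupt_fraction Fraction of trains given a jet-instability shape
#'   distortion.
#' @param corrupt_strength Relative amplitude of the distortion.
#' @param poisson Apply Poisson photon noise (\code{FALSE} gives the
#'   noiseless expectation, for exactness checks).
#' @param seed Integer seed; fixed seed gives bit-reproducible output.
#' @return Object of class \code{generator_config}.
#' @export
generator_config <- function(n_train_pairs = 50,
                             pulses_per_train = 175,
                             intra_train_rate = 564e3,
                             photons_per_pulse_scale = 7e10,
                             yield_c = 0.15,
                             rates = c(k_A = 0.5, k_B = 0.01),
                             jitter_sd = 1e-3,
                             corrupt_fraction = 0,
                             corrupt_strength = 0.1,
                             poisson = TRUE,
                             seed = 1L) {
  if (yield_c < 0 || yield_c > 1) stop("yield_c must be in [0, 1]")
  if (any(rates <= 0)) stop("rates must be positive (1/us)")
  if (corrupt_fraction < 0 || corrupt_fraction >= 1) stop("corrupt_fraction must be in [0, 1)")
  if (n_train_pairs < 1) stop("need at least one train pair")
  structure(list(n_train_pairs = as.integer(n_train_pairs),
                 pulses_per_train = as.integer(pulses_per_train),
                 intra_train_rate = intra_train_rate,
                 photons_per_pulse_scale = photons_per_pulse_scale,
                 yield_c = yield_c, rates = rates, jitter_sd = jitter_sd,
                 corrupt_fraction = corrupt_fraction,
                 corrupt_strength = corrupt_strength,
                 poisson = isTRUE(poisson), seed = as.integer(seed)),
            class = "generator_config")
}

# Compact coiled C-alpha trace on a spherical spiral: path length ~3.8 A per
# residue wound inside a ball, giving a protein-like Rg for ~100 residues.
compact_trace <- function(n_residues) {
  radius <- 3.3 * n_residues^(1 / 3)
  turns <- 3.8 * n_residues / (2 * radius)
  theta <- seq(0.05, pi - 0.05, length.out = n_residues)
  phi <- turns * theta
  cbind(radius * sin(theta) * cos(phi),
        radius * sin(theta) * sin(phi),
        radius * cos(theta))
}

#' Toy folded/partially-unfolded structure pairs
#'
#' Builds a compact coiled C-alpha trace as the native (folded) model and a
#' set of candidates in which a terminal span of residues is re-sampled as an
#' increasingly extended coil, emulating terminal-helix unfolding. Candidate
#' radii of gyration are always >= the native one, and the candidate set
#' spans dRg values through the 5-7 Å range where the largest structural
#' signals are expected.
#'
#' @param n_residues Chain length (default 125).
#' @param unfold_span Number of terminal residues re-sampled (default 30).
#' @param n_candidates Number of candidates at increasing extension.
#' @param seed Integer seed (same seed gives identical coordinates).
#' @return List with \code{native} (an [atomic_model()]), \code{candidates}
#'   (list of atomic models) and \code{delta_rg} (per-candidate dRg, Å).
#' @export
make_toy_structures <- function(n_residues = 125, unfold_span = 30,
                                n_candidates = 12, seed = 1L) {
  if (unfold_span >= n_residues) stop("unfold_span must be < n_residues")
  if (n_residues < 5) stop("n_residues too small for a meaningful trace")
  native_xyz <- compact_trace(n_residues)
  native <- atomic_model(native_xyz, rep("C", n_residues), id = "native")
  rg0 <- radius_of_gyration(native)
  centroid <- colMeans(native_xyz)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  ext_grid <- seq(0.05, 1, length.out = n_candidates)
  keep <- seq_len(n_residues - unfold_span)
  anchor <- native_xyz[n_residues - unfold_span, ]
  outward <- anchor - centroid
  outward <- outward / sqrt(sum(outward^2))
  candidates <- vector("list", n_candidates)
  for (i in seq_len(n_candidates)) {
    ext <- ext_grid[i]
    step <- 3.8 * (0.08 + 0.62 * ext)  # per-residue advance, A
    jit <- 1.2 * (1 - ext)             # residual disorder of the coil
    xyz <- native_xyz
    pos <- anchor
    for (j in seq_len(unfold_span)) {
      pos <- pos + step * outward + rnorm(3, sd = jit)
      xyz[n_residues - unfold_span + j, ] <- pos
    }
    candidates[[i]] <- atomic_model(xyz, rep("C", n_residues),
                                    id = sprintf("cand_%02d", i))
  }
  drg <- vapply(candidates, radius_of_gyration, numeric(1)) - rg0
  list(native = native, candidates = candidates, delta_rg = drg)
}

# Poisson draws; above 1e9 expected counts the normal limit is used so the
# draw stays within integer range.
pois_draw <- function(lam) {
  lam <- as.numeric(lam)
  out <- numeric(length(lam))
  big <- lam > 1e9
  if (any(!big)) out[!big] <- rpois(sum(!big), lam[!big])
  if (any(big)) out[big] <- round(rnorm(sum(big), lam[big], sqrt(lam[big])))
  out
}

# Smooth random q-polynomial with max|P| = 1, the shape of a jet artifact.
smooth_distortion <- function(q) {
  x <- (q - min(q)) / (max(q) - min(q)) * 2 - 1
  coef <- rnorm(4)
  p <- coef[1] + coef[2] * x + coef[3] * x^2 + coef[4] * x^3
  p <- p - mean(p)   # pure-scale component carries no shape information
  p / max(abs(p))
}

#' Simulate a pulse-train scattering series
#'
#' Generates alternating light/dark trains of 1D q-profiles. The dark-train
#' expectation at every pulse is \eqn{g \cdot S_{dark}(q)}; a light train adds
#' the photoinduced difference signal
#' \eqn{g\,(S_{dark}(q) + c\,\sum_i BS_i(q) C_i(t_j))}, with the sequential
#' kinetics \eqn{C_i(t)} evaluated on the intra-train delay grid.
#' \eqn{g = 1 + } common-mode jitter is drawn once per train. Observed counts
#' are Poisson around the expectation (per integrated q bin); corrupted
#' trains receive a smooth q-dependent shape distortion emulating jet
#' instability.
#'
#' @param config A [generator_config()].
#' @param dark_profile A \code{radial_profile} for the unexcited state; it is
#'   rescaled so its integrated intensity equals
#'   \code{photons_per_pulse_scale} (basis spectra are rescaled by the same
#'   factor, preserving relative signal size). Defaults to the toy native
#'   structure's Debye profile plus a solvent-dominated background on the
#'   standard 170-point grid.
#' @param basis_spectra q x n_states matrix of per-state difference shapes,
#'   in the same units as \code{dark_profile}. Defaults to the physical
#'   Debye difference profiles of toy candidate/native pairs; the default
#'   background is sized so the final state's signal peaks at
#'   \code{peak_rel} of the total dark scattering.
#' @param peak_rel Peak relative amplitude of the default final-state signal
#'   against the default background.
#' @return A \code{train_series} with a \code{truth} record.
#' @export
simulate_train_series <- function(config = generator_config(),
                                  dark_profile = NULL,
                                  basis_spectra = NULL,
                                  peak_rel = 1e-3) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  pick <- NULL
  background_raw <- NULL
  protein_raw <- NULL
  if (is.null(dark_profile) || is.null(basis_spectra)) {
    grid <- if (is.null(dark_profile)) q_grid() else dark_profile$q
    toy <- make_toy_structures(seed = config$seed)
    prot <- debye_profile(toy$native, grid)
    n_states <- if (length(config$rates) >= 2) 3L else 2L
    # distinct spectral signatures per state, as resolvable kinetic
    # components have: A = local thermal-scale rearrangement of the intact
    # fold (high-q-rich), B = partial expansion plus residual disorder,
    # C = full terminal unfolding near dRg = 6 A (low-q-rich)
    # state A: strong local rearrangement of a central (chromophore-pocket)
    # segment of the intact fold
    jiggle <- function(m, sd, id, span = seq_len(nrow(m$coords))) {
      xyz <- m$coords
      xyz[span, ] <- xyz[span, ] +
        matrix(rnorm(3 * length(span), sd = sd), ncol = 3)
      atomic_model(xyz, m$element, id = id)
    }
    # state B: the opposite (N-terminal) span partially extended — a
    # structural mode in a different part of the chain than the final state
    nxyz <- toy$native$coords
    nb <- 15
    dir_b <- nxyz[nb + 1, ] - colMeans(nxyz)
    dir_b <- dir_b / sqrt(sum(dir_b^2))
    posb <- nxyz[nb + 1, ]
    for (j in seq(nb, 1)) {
      posb <- posb + 2.6 * dir_b + rnorm(3, sd = 0.8)
      nxyz[j, ] <- posb
    }
    state_b <- atomic_model(nxyz, toy$native$element, id = "state_B")
    i_fin <- which.min(abs(toy$delta_rg - 6))
    states <- list(jiggle(toy$native, 2.2, "state_A", span = 45:80),
                   state_b,
                   toy$candidates[[i_fin]])
    if (n_states == 2) states <- states[c(2, 3)]
    pick <- c(if (n_states == 3) NA_integer_, NA_integer_, i_fin)
    bs <- vapply(states, function(m) {
      model_difference(m, toy$native, grid)$intensity
    }, numeric(length(grid$values)))
    if (is.null(basis_spectra)) basis_spectra <- bs
    if (is.null(dark_profile)) {
      # solvent-dominated background, sized so the final-state signal peaks
      # at peak_rel of the total dark scattering (the ~0.1% regime a dilute
      # protein in water produces)
      shape <- 0.6 + 0.4 * grid$values / max(grid$values)
      w0 <- max(abs(bs[, ncol(bs)]) / shape) / peak_rel
      background_raw <- w0 * shape
      protein_raw <- prot$intensity
      dark_profile <- radial_profile(grid, protein_raw + background_raw)
    }
  }
  q <- dark_profile$q
  nq <- length(q$values)
  if (nrow(basis_spectra) != nq) stop("basis spectra must share the dark profile's q grid")
  n_states <- ncol(basis_spectra)

  # photon-budget rescale; basis spectra share the dark profile's units and
  # are rescaled by the same factor
  alpha <- config$photons_per_pulse_scale / sum(dark_profile$intensity)
  s_dark <- alpha * dark_profile$intensity
  basis_spectra <- alpha * basis_spectra
  t_us <- pulse_time_grid(config$pulses_per_train, config$intra_train_rate)
  model <- sequential_model(n_states = n_states, rates = config$rates[seq_len(max(1, n_states - 1))])
  C <- concentration_profiles(model, t_us)
  signal <- config$yield_c * (basis_spectra %*% t(C))   # q x n_pulses

  n_trains <- 2L * config$n_train_pairs
  light_flag <- rep(c(TRUE, FALSE), config$n_train_pairs)
  n_corrupt <- floor(config$corrupt_fraction * n_trains)
  corrupt_ids <- if (n_corrupt > 0) sort(sample.int(n_trains, n_corrupt)) else integer(0)

  # common-mode factor drifts slowly across trains (jet thickness, X-ray
  # intensity): stationary AR(1), adjacent-train correlation 0.9
  rho <- 0.9
  drift <- numeric(n_trains)
  drift[1] <- rnorm(1)
  for (i in seq_len(n_trains - 1)) {
    drift[i + 1] <- rho * drift[i] + sqrt(1 - rho^2) * rnorm(1)
  }
  g_train <- 1 + config$jitter_sd * drift

  profiles <- vector("list", n_trains)
  for (i in seq_len(n_trains)) {
    g <- g_train[i]
    expec <- if (light_flag[i]) g * (s_dark + signal) else
      g * matrix(s_dark, nq, config$pulses_per_train)
    if (i %in% corrupt_ids) {
      expec <- expec * (1 + config$corrupt_strength * smooth_distortion(q$values))
    }
    if (any(expec < 0)) stop("negative expected counts: basis spectra too large for background")
    profiles[[i]] <- if (config$poisson) {
      matrix(pois_draw(expec), nq)
    } else expec
  }
  truth <- list(rates = config$rates, yield_c = config$yield_c,
                basis_spectra = basis_spectra, concentrations = C,
                s_dark = s_dark, corrupt_ids = corrupt_ids,
                state_candidates = pick,
                background = if (!is.null(background_raw)) alpha * background_raw,
                dark_protein = if (!is.null(protein_raw)) alpha * protein_raw)
  train_series(profiles, q, t_us, light_flag, truth = truth)
}

#' Inject jet-instability distortions into specific trains
#'
#' Multiplies the listed trains' profiles by a smooth q-dependent factor
#' \eqn{1 + strength \cdot P(q)}; at the default strength the distorted
#' trains fall below the 0.99995 profile-correlation filter threshold.
#' Injected ids are recorded in the series' truth block.
#'
#' @param series A \code{train_series}.
#' @param ids Train indices to distort.
#' @param strength Relative distortion amplitude (0 leaves the series
#'   unchanged).
#' @param seed Optional seed for the distortion shape.
#' @return The modified \code{train_series}.
#' @export
inject_instability <- function(series, ids, strength = 0.1, seed = NULL) {
  if (length(ids) > 0 && (any(ids < 1) || any(ids > length(series$profiles)))) {
    stop("train ids out of range")
  }
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  if (strength > 0) {
    for (i in ids) {
      fac <- 1 + strength * smooth_distortion(series$q$values)
      series$profiles[[i]] <- series$profiles[[i]] * fac
    }
  }
  series$truth$corrupt_ids <- sort(union(series$truth$corrupt_ids, ids))
  series
}
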