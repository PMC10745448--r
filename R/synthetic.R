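#' Configuration for the factorial spectra simulator
#'
#' Bundles everything [buildDesign()], [targetErrorCovariance()] and
#' [simulateSpectra()] need: the wavelength grid, the factor levels of a
#' full-factorial replicate design, per-sample baseline band parameters,
#' the magnitudes of the systematic factor effects, and the parameters of
#' the structured measurement noise.
#'
#' The defaults emulate a benchtop-replicate study on a miniaturized NIR
#' instrument: 236 channels over 972-1701 nm, 15 replicates x 4 samples x
#' 3 sessions x 2 background timings (360 acquisitions). Passing
#' `powerSupply = c("mains", "battery")` (with `channels = 74`,
#' `wlRange = c(1351, 2559)`) emulates the handheld-scanner design with
#' 720 acquisitions.
#'
#' Noise is Gaussian with covariance `Sigma = D^(1/2) R D^(1/2)`: `D` is a
#' smooth heteroscedastic variance profile (noise inflated towards the
#' detector edges) and `R = w * R_smooth + (1 - w) * R_band` mixes a
#' squared-exponential correlation (smooth drift-like error) with an AR(1)
#' band correlation `rho^|i-j|` (short-range channel correlation).
#'
#' @param channels number of wavelength channels.
#' @param wlRange numeric length-2, wavelength range in nm.
#' @param samples,sessions,replicates level counts of the design factors.
#' @param backgroundTimings character levels of the background-timing
#'   factor (`"per-sample"`: background before each sample; `"session-start"`:
#'   background only at the start of the session).
#' @param powerSupply optional character levels of the power-supply factor;
#'   `NULL` omits the factor.
#' @param configLabel instrument-configuration label stored in the design.
#' @param sessionOffsetScale sd of the smooth additive session offsets
#'   (reflectance units).
#' @param backgroundDriftSlope additive drift per replicate step, applied
#'   only at the `"session-start"` background level.
#' @param powerSupplyOffset additive offset of the second power-supply
#'   level.
#' @param scatterLogSd sd of the log-normal multiplicative scatter factor.
#' @param additiveOffsetSd sd of the per-spectrum additive baseline offset.
#' @param noiseSd base per-channel error sd (reflectance units); the
#'   heteroscedastic profile doubles it at the range edges.
#' @param rho AR(1) correlation decay of the banded noise, in `[0, 1)`.
#' @param smoothWeight weight `w` in `[0, 1]` of the smooth correlation
#'   component.
#' @param smoothKernelWidth width (in channels) of the squared-exponential
#'   kernel; default `channels / 10`.
#' @param seed root RNG seed.
#' @return a `SimConfig` list.
#' @export
simConfig <- function(channels = 236,
                      wlRange = c(972, 1701),
                      samples = 4,
                      sessions = 3,
                      replicates = 15,
                      backgroundTimings = c("per-sample", "session-start"),
                      powerSupply = NULL,
                      configLabel = "simulated",
                      sessionOffsetScale = 0.01,
                      backgroundDriftSlope = 0.002,
                      powerSupplyOffset = 0.005,
                      scatterLogSd = 0.02,
                      additiveOffsetSd = 0.002,
                      noiseSd = 0.003,
                      rho = 0.9,
                      smoothWeight = 0.3,
                      smoothKernelWidth = NULL,
                      seed = 1) {
    stopifnot(channels >= 2, length(wlRange) == 2, wlRange[1] < wlRange[2])
    counts <- c(samples = samples, sessions = sessions,
                replicates = replicates,
                backgroundTimings = length(backgroundTimings))
    if (any(counts < 1))
        stop("every design factor needs at least one level (got zero ",
             paste(names(counts)[counts < 1], collapse = ", "), ")")
    if (!is.null(powerSupply) && length(powerSupply) < 1)
        stop("powerSupply must be NULL or a non-empty level vector")
    scales <- c(sessionOffsetScale, backgroundDriftSlope, powerSupplyOffset,
                scatterLogSd, additiveOffsetSd, noiseSd)
    if (any(scales < 0)) stop("effect and noise scales must be >= 0")
    if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
    if (smoothWeight < 0 || smoothWeight > 1)
        stop("smoothWeight must be in [0, 1]")
    if (is.null(smoothKernelWidth)) smoothKernelWidth <- channels / 10
    cfg <- list(channels = as.integer(channels), wlRange = wlRange,
                samples = as.integer(samples),
                sessions = as.integer(sessions),
                replicates = as.integer(replicates),
                backgroundTimings = backgroundTimings,
                powerSupply = powerSupply, configLabel = configLabel,
                sessionOffsetScale = sessionOffsetScale,
                backgroundDriftSlope = backgroundDriftSlope,
                powerSupplyOffset = powerSupplyOffset,
                scatterLogSd = scatterLogSd,
                additiveOffsetSd = additiveOffsetSd,
                noiseSd = noiseSd, rho = rho, smoothWeight = smoothWeight,
                smoothKernelWidth = smoothKernelWidth,
                seed = as.integer(seed))
    class(cfg) <- "SimConfig"
    cfg
}

#' @export
print.SimConfig <- function(x, ...) {
    n <- x$replicates * x$samples * x$sessions *
        length(x$backgroundTimings) * max(1L, length(x$powerSupply))
    cat("SimConfig:", x$channels, "channels over",
        paste(x$wlRange, collapse = "-"), "nm;",
        n, "acquisitions\n")
    invisible(x)
}

.simWavelengths <- function(cfg)
    seq(cfg$wlRange[1], cfg$wlRange[2], length.out = cfg$channels)

# Per-sample baseline: offset plus Gaussian reflectance bands on the nm
# axis. Samples 1-2 are darker (low reflectance), 3-4 brighter, echoing
# compact pills vs whitish tablets; further samples cycle with jittered
# band positions so any sample count is usable.
.sampleBaseline <- function(cfg, k) {
    wl <- .simWavelengths(cfg)
    span <- diff(cfg$wlRange)
    base <- c(0.25, 0.32, 0.55, 0.65)[((k - 1L) %% 4L) + 1L]
    centers <- cfg$wlRange[1] + span * (c(0.25, 0.55, 0.8) +
                                        0.02 * ((k - 1L) %% 4L))
    widths <- span * c(0.08, 0.12, 0.06)
    amps <- c(0.10, 0.15, 0.08) * (0.8 + 0.1 * ((k - 1L) %% 4L))
    bands <- vapply(seq_along(centers), function(b)
        amps[b] * exp(-((wl - centers[b])^2) / (2 * widths[b]^2)),
        numeric(length(wl)))
    base + rowSums(bands)
}

#' Build a full-factorial acquisition design
#'
#' Crosses every configured factor level, one row per acquisition, with
#' `replicate_order` nested as the innermost (fastest-varying) index.
#'
#' @param cfg a [simConfig()].
#' @return a data.frame with factor columns `sample`, `session`,
#'   `replicate_order`, `background_timing`, optionally `power_supply`, and
#'   `instrument_config`.
#' @examples
#' nrow(buildDesign(simConfig()))  # 360
#' @export
buildDesign <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    lv <- list(replicate_order = seq_len(cfg$replicates),
               sample = paste0("sample", seq_len(cfg$samples)),
               session = as.character(seq_len(cfg$sessions)),
               background_timing = cfg$backgroundTimings)
    if (!is.null(cfg$powerSupply)) lv$power_supply <- cfg$powerSupply
    d <- expand.grid(lv, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
    d$instrument_config <- cfg$configLabel
    ord <- c("sample", "session", "replicate_order", "background_timing",
             if (!is.null(cfg$powerSupply)) "power_supply",
             "instrument_config")
    d <- d[ord]
    d[] <- lapply(d, function(col) factor(as.character(col),
                                          levels = unique(as.character(col))))
    d
}

#' Ground-truth error covariance of the simulator
#'
#' Assembles `Sigma = D^(1/2) R D^(1/2)` from the configured variance
#' profile and the mixed smooth/banded correlation (see [simConfig()]).
#' Used both to draw the simulated noise and as the reference that
#' covariance-recovery tests compare against.
#'
#' @param cfg a [simConfig()].
#' @return symmetric positive-semidefinite `channels x channels` matrix.
#' @export
targetErrorCovariance <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    p <- cfg$channels
    idx <- seq_len(p)
    # heteroscedastic profile: sd doubled at the detector edges
    rel <- (idx - (p + 1) / 2) / ((p - 1) / 2)
    sdProf <- cfg$noiseSd * (1 + rel^2)
    Rband <- cfg$rho^abs(outer(idx, idx, "-"))
    ell <- cfg$smoothKernelWidth
    Rsmooth <- exp(-outer(idx, idx, "-")^2 / (2 * ell^2))
    R <- cfg$smoothWeight * Rsmooth + (1 - cfg$smoothWeight) * Rband
    Sigma <- outer(sdProf, sdProf) * R
    Sigma <- (Sigma + t(Sigma)) / 2
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(abs(ev), 1)) {
        warning("assembled covariance not PSD numerically; ",
                "clipping negative eigenvalues at 0")
        es <- eigen(Sigma, symmetric = TRUE)
        Sigma <- es$vectors %*% (pmax(es$values, 0) * t(es$vectors))
        Sigma <- (Sigma + t(Sigma)) / 2
    }
    Sigma
}

# Symmetric PSD square root (eigenvalue clipping at 0); tolerates the
# all-zero covariance of a noiseless configuration, unlike chol().
.psdSqrt <- function(Sigma) {
    es <- eigen(Sigma, symmetric = TRUE)
    es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
}

#' Simulate design-annotated replicate spectra
#'
#' Each acquisition is
#' `m_i * (baseline_sample + offset_session + drift + offset_supply) + a_i + eps_i`
#' with `m_i` log-normal multiplicative scatter, `a_i` a Gaussian additive
#' offset and `eps_i` Gaussian noise with covariance
#' [targetErrorCovariance()]. Session offsets are smooth random curves;
#' the background drift is linear in replicate order and present only at
#' the `"session-start"` background level. A single root seed first draws
#' the session curves, then one substream seed per acquisition, so results
#' are reproducible and stable under row subsetting.
#'
#' @param design a design as returned by [buildDesign()] (or any design
#'   with the same factor columns at levels consistent with `cfg`).
#' @param cfg a [simConfig()].
#' @param seed root seed; defaults to `cfg$seed`.
#' @return a [SpectraSet-class].
#' @export
simulateSpectra <- function(design, cfg, seed = cfg$seed) {
    stopifnot(inherits(cfg, "SimConfig"))
    needed <- c("sample", "session", "replicate_order", "background_timing")
    miss <- setdiff(needed, names(design))
    if (length(miss))
        stop("design lacks factor column(s): ", paste(miss, collapse = ", "))
    n <- nrow(design)
    p <- cfg$channels
    wl <- .simWavelengths(cfg)
    sqrtSigma <- .psdSqrt(targetErrorCovariance(cfg))

    set.seed(seed)
    # smooth session offsets: random weights on a low-order cosine basis
    basis <- vapply(1:3, function(k)
        cos(pi * k * seq(0, 1, length.out = p)), numeric(p))
    sessLevels <- as.character(seq_len(cfg$sessions))
    sessOffsets <- vapply(sessLevels, function(s)
        as.numeric(basis %*% stats::rnorm(3, 0, cfg$sessionOffsetScale)),
        numeric(p))
    rowSeeds <- sample.int(.Machine$integer.max - 1L, n)

    baselines <- vapply(seq_len(cfg$samples), function(k)
        .sampleBaseline(cfg, k), numeric(p))
    sampleLevels <- paste0("sample", seq_len(cfg$samples))
    supplyLevels <- cfg$powerSupply

    m <- matrix(0, n, p)
    for (i in seq_len(n)) {
        si <- match(as.character(design$sample[i]), sampleLevels)
        se <- match(as.character(design$session[i]), sessLevels)
        if (is.na(si) || is.na(se))
            stop("design row ", i, " has levels not covered by cfg")
        mu <- baselines[, si] + sessOffsets[, se]
        if (as.character(design$background_timing[i]) == "session-start") {
            ord <- as.numeric(as.character(design$replicate_order[i]))
            mu <- mu + cfg$backgroundDriftSlope * (ord - 1)
        }
        if (!is.null(supplyLevels) &&
            as.character(design$power_supply[i]) == supplyLevels[
                min(2L, length(supplyLevels))] &&
            length(supplyLevels) > 1L)
            mu <- mu + cfg$powerSupplyOffset
        set.seed(rowSeeds[i])
        mi <- exp(stats::rnorm(1, 0, cfg$scatterLogSd))
        ai <- stats::rnorm(1, 0, cfg$additiveOffsetSd)
        eps <- as.numeric(sqrtSigma %*% stats::rnorm(p))
        m[i, ] <- mi * mu + ai + eps
    }
    SpectraSet(m, wl, design)
}
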