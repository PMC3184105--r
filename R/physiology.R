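.checkGrowthSeries <- function(s) {
  need <- c("time", "total_pfu", "infective_centers")
  if (!is.data.frame(s) || !all(need %in% names(s)))
    stop(sprintf("growth series must be a data.frame with columns %s",
                 paste(need, collapse = ", ")))
  if (nrow(s) < 5L) stop("growth series needs at least 5 time points")
  if (is.unsorted(s$time, strictly = TRUE))
    stop("time must be strictly increasing")
  if (any(s$total_pfu < 0, na.rm = TRUE) ||
      any(s$infective_centers < 0, na.rm = TRUE))
    stop("titers must be non-negative")
  if (s$time[1] > 5)
    warning("first sample is later than 5 min post-infection; early-phase estimates may be biased")
  invisible(TRUE)
}

# Index of the first point exceeding rise_factor x the running geometric-mean
# baseline, or NA if the series never rises. Titers are log-distributed, so
# the baseline is a geometric mean of the pre-rise points.
.riseIndex <- function(x, rise_factor) {
  x <- as.numeric(x)
  if (any(x <= 0)) x[x <= 0] <- min(x[x > 0]) * 1e-6    # guard zeros
  base_log <- log(x[1])
  k <- 1L
  for (i in 2:length(x)) {
    if (log(x[i]) > log(rise_factor) + base_log)
      return(list(index = i, baseline = exp(base_log)))
    base_log <- (base_log * k + log(x[i])) / (k + 1L)
    k <- k + 1L
  }
  list(index = NA_integer_, baseline = exp(base_log))
}

# Plateau after the rise ends: smooth the log-titers with a centered 3-point
# mean, locate the first post-rise point where the smoothed successive
# relative change falls below `tol` (the rise has ended), and return the
# geometric mean of the raw points from there on.
.plateauValue <- function(x, from, tol = 0.1) {
  x <- as.numeric(x)
  n <- length(x)
  if (from >= n) return(x[n])
  lx <- log(x)
  sm <- lx
  for (i in seq(max(from, 2L), n - 1L)) sm[i] <- mean(lx[(i - 1):(i + 1)])
  start <- n
  for (i in seq(from, n - 1L)) {
    if (abs(sm[i + 1L] - sm[i]) < log(1 + tol)) { start <- i + 1L; break }
  }
  exp(mean(lx[start:n]))
}

#' One-step growth-curve metrics
#'
#' Estimates the eclipse period (first rise of total phage, i.e. first
#' appearance of mature intracellular phage revealed by chloroform), the
#' latent period (first rise of infective centers / free phage, i.e. onset of
#' lysis) and the burst size (plateau total phage over the baseline of
#' infective centers). Rise detection uses a `rise_factor` multiple of the
#' running geometric-mean baseline; the plateau is the trailing stretch over
#' which the (smoothed) successive change stays below 10%.
#'
#' @param s data.frame with columns `time` (minutes), `total_pfu`,
#'   `infective_centers` (PFU/mL), optionally `od600`, `cfu_survivors`.
#' @param rise_factor Threshold multiple of baseline (default 2).
#' @param plateau_tol Relative successive change defining the plateau
#'   (default 0.1).
#' @return A list of class `growth_summary`: `eclipse_min`, `latent_min`,
#'   `burst_size`, `plateau_pfu`, `baseline_ic`, `baseline_total`,
#'   `rise_detected`.
#' @export
oneStepMetrics <- function(s, rise_factor = 2.0, plateau_tol = 0.1) {
  .checkGrowthSeries(s)
  stopifnot(rise_factor > 1)
  rt <- .riseIndex(s$total_pfu, rise_factor)
  ri <- .riseIndex(s$infective_centers, rise_factor)
  rise_detected <- !is.na(rt$index)
  eclipse <- if (rise_detected) s$time[rt$index] else NA_real_
  latent <- if (!is.na(ri$index)) s$time[ri$index] else NA_real_
  plateau <- if (rise_detected)
    .plateauValue(s$total_pfu, rt$index, plateau_tol) else NA_real_
  burst <- if (rise_detected) plateau / ri$baseline else NA_real_
  if (rise_detected && !is.na(latent) && eclipse > latent)
    warning("estimated eclipse exceeds latent period; check the series")
  structure(list(eclipse_min = eclipse, latent_min = latent,
                 burst_size = burst, plateau_pfu = plateau,
                 baseline_ic = ri$baseline, baseline_total = rt$baseline,
                 rise_detected = rise_detected),
            class = "growth_summary")
}

#' @export
print.growth_summary <- function(x, ...) {
  if (!x$rise_detected) {
    cat("one-step growth: no rise detected\n")
  } else {
    cat(sprintf(
      "one-step growth: eclipse %.4g min, latent %.4g min, burst %.4g phage/cell\n",
      x$eclipse_min, x$latent_min, x$burst_size))
  }
  invisible(x)
}

#' Lysis-inhibition assessment from a high-MOI OD trajectory
#'
#' Lysis onset is the first time the OD falls below 90% of its running
#' maximum. The inhibition flag is raised when the culture keeps growing
#' after infection (maximum OD at least `od_ratio_threshold` times the OD at
#' infection) and lysis is delayed beyond `onset_threshold_min`.
#'
#' @param s data.frame with `time` and `od600` (plus titer columns if a
#'   high-MOI burst size is wanted); may carry an `moi` attribute.
#' @param od_ratio_threshold Minimum max-OD/initial-OD ratio (default 2).
#' @param onset_threshold_min Minimum lysis-onset time, minutes (default 60).
#' @param rise_factor Passed to the burst computation when titers are present.
#' @return A list of class `lysis_report`: `od_ratio_max`, `lysis_onset_min`,
#'   `inhibition_flag`, `high_moi_burst`, `moi`.
#' @export
lysisInhibition <- function(s, od_ratio_threshold = 2.0,
                            onset_threshold_min = 60, rise_factor = 2.0) {
  if (!is.data.frame(s) || !all(c("time", "od600") %in% names(s)))
    stop("lysis assessment needs 'time' and 'od600' columns")
  if (any(is.na(s$od600))) stop("od600 contains missing values")
  od <- s$od600
  ratio_max <- max(od) / od[1]
  run_max <- cummax(od)
  below <- which(od < 0.9 * run_max)
  onset <- if (length(below)) s$time[below[1]] else NA_real_
  if (is.na(onset)) {
    warning("OD never declines; inhibition flag based on the OD ratio only")
    flag <- ratio_max >= od_ratio_threshold
  } else {
    flag <- ratio_max >= od_ratio_threshold && onset >= onset_threshold_min
  }
  burst <- NA_real_
  if (all(c("total_pfu", "infective_centers") %in% names(s))) {
    gm <- suppressWarnings(tryCatch(oneStepMetrics(s, rise_factor = rise_factor),
                                    error = function(e) NULL))
    if (!is.null(gm) && gm$rise_detected) burst <- gm$burst_size
  }
  structure(list(od_ratio_max = ratio_max, lysis_onset_min = onset,
                 inhibition_flag = flag, high_moi_burst = burst,
                 moi = attr(s, "moi")),
            class = "lysis_report")
}

#' @export
print.lysis_report <- function(x, ...) {
  cat(sprintf(
    "lysis: max OD ratio %.2f, onset %s min, inhibition %s%s\n",
    x$od_ratio_max,
    ifelse(is.na(x$lysis_onset_min), "undefined", format(x$lysis_onset_min)),
    x$inhibition_flag,
    if (!is.na(x$high_moi_burst))
      sprintf(", burst %.4g phage/cell", x$high_moi_burst) else ""))
  invisible(x)
}

#' Classify isotope incorporation from labelling time series
#'
#' Fits least-squares slopes of acid-precipitable counts versus time for the
#' infected culture and an uninfected (or positive) control. Incorporation is
#' flagged when the infected slope exceeds `min_fraction` of the control
#' slope and is itself significantly positive (one-sided t-test on the slope
#' at level `alpha`).
#'
#' @param infected,control data.frames with `time` (minutes) and `cpm`
#'   columns; at least 4 points each, overlapping time ranges.
#' @param min_fraction Fraction of the control slope the infected slope must
#'   exceed (default 0.1).
#' @param alpha Significance level for the slope test (default 0.05).
#' @return A list of class `label_result`: `slope_infected`, `slope_control`,
#'   `intercepts`, `p_slope_infected`, `incorporation_flag`.
#' @export
labelUptake <- function(infected, control, min_fraction = 0.1, alpha = 0.05) {
  for (nm in c("infected", "control")) {
    s <- get(nm)
    if (!is.data.frame(s) || !all(c("time", "cpm") %in% names(s)))
      stop(sprintf("%s series needs 'time' and 'cpm' columns", nm))
    if (nrow(s) < 4L)
      stop(sprintf("%s series has fewer than 4 points", nm))
    if (any(s$cpm < 0)) stop(sprintf("%s cpm must be non-negative", nm))
  }
  if (min(infected$time) > max(control$time) ||
      min(control$time) > max(infected$time))
    stop("infected and control series do not overlap in time")

  fit_i <- stats::lm(cpm ~ time, data = infected)
  fit_c <- stats::lm(cpm ~ time, data = control)
  b_i <- unname(stats::coef(fit_i)["time"])
  b_c <- unname(stats::coef(fit_c)["time"])
  if (b_c <= 0)
    stop("control slope is not positive: label or control failure")
  # a perfect (noise-free) fit gives se = 0; handled explicitly below
  se_i <- suppressWarnings(
    summary(fit_i)$coefficients["time", "Std. Error"])
  p_i <- if (is.na(se_i) || se_i == 0) {
    if (b_i > 0) 0 else 1
  } else {
    stats::pt(b_i / se_i, df = stats::df.residual(fit_i), lower.tail = FALSE)
  }
  flag <- (b_i > min_fraction * b_c) && (p_i < alpha)
  structure(list(slope_infected = b_i, slope_control = b_c,
                 intercept_infected = unname(stats::coef(fit_i)[1]),
                 intercept_control = unname(stats::coef(fit_c)[1]),
                 p_slope_infected = p_i,
                 incorporation_flag = flag),
            class = "label_result")
}

#' @export
print.label_result <- function(x, ...) {
  cat(sprintf(
    "label uptake: infected slope %.3g cpm/min vs control %.3g; incorporation %s\n",
    x$slope_infected, x$slope_control, x$incorporation_flag))
  invisible(x)
}

#' Read a delimited growth or label table
#'
#' Comma- or tab-delimited with a header; growth tables need
#' `time,total_pfu,infective_centers` (optionally `od600`, `cfu_survivors`),
#' label tables `time,cpm`.
#'
#' @param path File path.
#' @param moi Optional declared multiplicity of infection, stored as an
#'   attribute.
#' @return A data.frame.
#' @export
readGrowthTable <- function(path, moi = NULL) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  out <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!is.null(moi)) attr(out, "moi") <- moi
  out
}
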