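# Synthetic fixtures: canonical shapes of known fractal dimension for
# validating the box-counting estimator, pseudo-trabecular textures for
# exercising the full pipeline, and cohort simulation parameterized by the
# published per-cell descriptive statistics.

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state,
# so every generator is a pure function of (parameters, seed).
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Sierpinski carpet
#'
#' Deterministic `3^depth x 3^depth` binary carpet with `8^depth`
#' foreground pixels; its box-counting dimension is `log(8)/log(3)`
#' (about 1.8928), making it the canonical estimator-validation fixture.
#'
#' @param depth recursion level, 1 to 6.
#' @return Logical matrix.
#' @export
make_sierpinski_carpet <- function(depth) {
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 1L || depth > 6L)
    stop("depth must be an integer in [1, 6]", call. = FALSE)
  cell <- matrix(1, 3L, 3L); cell[2L, 2L] <- 0
  carpet <- cell
  for (i in seq_len(depth - 1L)) carpet <- kronecker(carpet, cell)
  carpet > 0
}

#' Canonical dimension-1 fixture: a straight 1-px-wide line
#'
#' @param length line length in pixels.
#' @param orientation `"horizontal"` or `"vertical"`.
#' @return Logical square matrix of side `length` containing the line.
#' @export
make_line <- function(length, orientation = c("horizontal", "vertical")) {
  orientation <- match.arg(orientation)
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("length must be positive", call. = FALSE)
  out <- matrix(FALSE, length, length)
  mid <- (length + 1L) %/% 2L
  if (orientation == "horizontal") out[mid, ] <- TRUE else out[, mid] <- TRUE
  out
}

#' Canonical dimension-2 fixture: a filled rectangle
#'
#' @param width,height rectangle extent in pixels.
#' @return Logical matrix, all foreground.
#' @export
make_filled_rect <- function(width, height) {
  width <- as.integer(width); height <- as.integer(height)
  if (is.na(width) || is.na(height) || width < 1L || height < 1L)
    stop("dimensions must be positive", call. = FALSE)
  matrix(TRUE, height, width)
}

#' Pseudo-trabecular grayscale texture
#'
#' Spectral synthesis of power-law (1/f^beta) noise rescaled to 8 bits.
#' The complexity knob maps linearly to the spectral exponent
#' `beta = 3.5 - 2 * complexity`, spanning the fractional-Brownian regime
#' (white noise, beta < 1.5, is avoided because there box-count estimates
#' saturate): low complexity gives smooth, blobby
#' fields, high complexity injects high spatial frequencies, emulating the
#' range from sparse to dense trabecular patterns whose space-filling
#' complexity the FD quantifies. It does not render anatomy (condylar
#' outline, cortical rim, superimpositions).
#'
#' @param size image side in pixels (>= 64).
#' @param complexity roughness in \[0, 1\].
#' @param seed RNG seed; same seed gives an identical image.
#' @return Grayscale integer matrix spanning the full \[0, 255\] range.
#' @export
make_trabecular_texture <- function(size = 128L, complexity = 0.5, seed = 1L) {
  size <- as.integer(size)
  if (is.na(size) || size < 64L) stop("size must be >= 64", call. = FALSE)
  if (!is.numeric(complexity) || complexity < 0 || complexity > 1)
    stop("complexity must lie in [0, 1]", call. = FALSE)
  beta <- 3.5 - 2 * complexity
  with_seed(seed, {
    phase <- matrix(stats::runif(size^2, 0, 2 * pi), size, size)
    f <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1)) / size
    fr <- matrix(f, size, size)         # frequency along rows
    fc <- matrix(f, size, size, byrow = TRUE)
    radius <- sqrt(fr^2 + fc^2)
    amp <- ifelse(radius == 0, 0, radius^(-beta / 2))
    spec <- amp * exp(1i * phase)
    field <- Re(stats::fft(spec, inverse = TRUE)) / size^2
    rng <- range(field)
    matrix(as.integer(round((field - rng[1L]) / diff(rng) * 255)), size, size)
  })
}

#' Published per-cell descriptive statistics of condylar FD
#'
#' The reference grid of group sizes, means and standard deviations of
#' left- and right-condyle fractal dimension for TMD patients and
#' age-matched controls, stratified by age band and gender, with the
#' per-age-band overall rows. These cells parameterize [simulate_cohort()]
#' and anchor the descriptive-statistics tests.
#'
#' Cell counts follow the left-condyle block of the source tables; the
#' right-condyle block of the control table prints slightly different
#' gender counts for the same subjects, which cannot both hold and are not
#' used.
#'
#' @return Data frame with columns `group`, `age_group`, `stratum`
#'   (male/female/overall), `n`, `lc_mean`, `lc_sd`, `rc_mean`, `rc_sd`.
#' @export
condyle_fd_reference_cells <- function() {
  ages <- c("18-29", "30-39", "40-49", ">=50")
  rbind(
    data.frame(group = "patient", age_group = ages, stratum = "male",
               n = c(12L, 7L, 13L, 15L),
               lc_mean = c(1.2539, 1.2510, 1.2254, 1.2150),
               lc_sd   = c(0.0909, 0.0511, 0.0911, 0.0934),
               rc_mean = c(1.2675, 1.2520, 1.1820, 1.2392),
               rc_sd   = c(0.0858, 0.0674, 0.0986, 0.0682)),
    data.frame(group = "patient", age_group = ages, stratum = "female",
               n = c(12L, 26L, 13L, 12L),
               lc_mean = c(1.1857, 1.2339, 1.2122, 1.2103),
               lc_sd   = c(0.1066, 0.0758, 0.0722, 0.0700),
               rc_mean = c(1.2367, 1.2406, 1.1920, 1.1938),
               rc_sd   = c(0.0914, 0.0821, 0.0788, 0.0852)),
    data.frame(group = "patient", age_group = ages, stratum = "overall",
               n = c(24L, 33L, 26L, 27L),
               lc_mean = c(1.2198, 1.2376, 1.2188, 1.2129),
               lc_sd   = c(0.1030, 0.0709, 0.0808, 0.0823),
               rc_mean = c(1.2521, 1.2430, 1.1870, 1.2191),
               rc_sd   = c(0.0881, 0.0783, 0.0876, 0.0781)),
    data.frame(group = "control", age_group = ages, stratum = "male",
               n = c(13L, 12L, 14L, 15L),
               lc_mean = c(1.3008, 1.2893, 1.2899, 1.2497),
               lc_sd   = c(0.0645, 0.0847, 0.0730, 0.0562),
               rc_mean = c(1.2412, 1.2392, 1.3212, 1.2669),
               rc_sd   = c(0.1455, 0.0958, 0.1025, 0.0757)),
    data.frame(group = "control", age_group = ages, stratum = "female",
               n = c(11L, 21L, 12L, 12L),
               lc_mean = c(1.3462, 1.3028, 1.2850, 1.3007),
               lc_sd   = c(0.0434, 0.0860, 0.0830, 0.0634),
               rc_mean = c(1.3004, 1.3095, 1.3265, 1.2361),
               rc_sd   = c(0.1103, 0.0963, 0.0727, 0.1106)),
    data.frame(group = "control", age_group = ages, stratum = "overall",
               n = c(24L, 33L, 26L, 27L),
               lc_mean = c(1.3216, 1.2979, 1.2877, 1.2724),
               lc_sd   = c(0.0594, 0.0844, 0.0762, 0.0638),
               rc_mean = c(1.2708, 1.2733, 1.3245, 1.2532),
               rc_sd   = c(0.1298, 0.1010, 0.0834, 0.0922))
  )
}

#' Default cohort simulation parameters
#'
#' One row per (group, age band, gender) cell: size, LC/RC FD means and
#' SDs, taken from [condyle_fd_reference_cells()] (gender strata only;
#' 220 subjects in total, 110 per group).
#'
#' @return Data frame with columns `group`, `age_group`, `gender`, `n`,
#'   `lc_mean`, `lc_sd`, `rc_mean`, `rc_sd`.
#' @export
default_cohort_params <- function() {
  cells <- condyle_fd_reference_cells()
  cells <- cells[cells$stratum != "overall", ]
  names(cells)[names(cells) == "stratum"] <- "gender"
  rownames(cells) <- NULL
  cells
}

age_band_range <- function(age_group) {
  switch(age_group,
         "18-29" = c(18L, 29L), "30-39" = c(30L, 39L),
         "40-49" = c(40L, 49L), ">=50" = c(50L, 75L),
         stop("unknown age band: ", age_group, call. = FALSE))
}

#' Simulate a cohort of subjects with per-condyle FD values
#'
#' For every parameter cell, draws (LC_FD, RC_FD) jointly normal with the
#' cell's means/SDs and between-condyle correlation `rho`, truncated to
#' (0, 2] by redrawing; ages are uniform within the band (the >= 50 band
#' is capped at 75, the study's upper age limit).
#'
#' @param params cell table as from [default_cohort_params()].
#' @param rho within-subject correlation between left and right condyle FD
#'   (not reported by the source study; 0.5 by default).
#' @param seed RNG seed.
#' @return Data frame with columns `subject_id`, `age`, `gender`, `group`,
#'   `lc_fd`, `rc_fd`; one row per subject.
#' @export
#' @examples
#' cohort <- simulate_cohort(seed = 42)
#' table(cohort$group)
simulate_cohort <- function(params = default_cohort_params(), rho = 0.5,
                            seed = 42L) {
  req <- c("group", "age_group", "gender", "n",
           "lc_mean", "lc_sd", "rc_mean", "rc_sd")
  missing_cols <- setdiff(req, names(params))
  if (length(missing_cols) > 0L)
    stop("params is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (any(params$lc_sd <= 0) || any(params$rc_sd <= 0))
    stop("all SDs must be > 0", call. = FALSE)
  if (any(params$n < 0)) stop("cell sizes must be >= 0", call. = FALSE)
  if (!is.numeric(rho) || rho <= -1 || rho >= 1)
    stop("rho must lie strictly inside (-1, 1)", call. = FALSE)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(params)), function(i) {
      cell <- params[i, ]
      if (cell$n == 0L) return(NULL)
      sigma <- matrix(c(cell$lc_sd^2, rho * cell$lc_sd * cell$rc_sd,
                        rho * cell$lc_sd * cell$rc_sd, cell$rc_sd^2), 2L, 2L)
      fd <- MASS::mvrnorm(cell$n, mu = c(cell$lc_mean, cell$rc_mean),
                          Sigma = sigma)
      fd <- matrix(fd, ncol = 2L)
      bad <- which(fd[, 1L] <= 0 | fd[, 1L] > 2 | fd[, 2L] <= 0 | fd[, 2L] > 2)
      while (length(bad) > 0L) {
        fd[bad, ] <- MASS::mvrnorm(length(bad),
                                   mu = c(cell$lc_mean, cell$rc_mean),
                                   Sigma = sigma)
        bad <- which(fd[, 1L] <= 0 | fd[, 1L] > 2 |
                     fd[, 2L] <= 0 | fd[, 2L] > 2)
      }
      band <- age_band_range(cell$age_group)
      data.frame(age = sample(band[1L]:band[2L], cell$n, replace = TRUE),
                 gender = cell$gender, group = cell$group,
                 lc_fd = fd[, 1L], rc_fd = fd[, 2L])
    })
    cohort <- do.call(rbind, rows)
    cohort$subject_id <- sprintf("S%03d", seq_len(nrow(cohort)))
    rownames(cohort) <- NULL
    cohort[, c("subject_id", "age", "gender", "group", "lc_fd", "rc_fd")]
  })
}

#' Derive the age band of an age in years
#'
#' @param age integer vector of ages (>= 18).
#' @return Character vector of bands `18-29`, `30-39`, `40-49`, `>=50`.
#' @export
age_to_band <- function(age) {
  if (any(age < 18)) stop("study age range starts at 18", call. = FALSE)
  cut(age, breaks = c(18, 30, 40, 50, Inf), right = FALSE,
      labels = c("18-29", "30-39", "40-49", ">=50")) |> as.character()
}
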