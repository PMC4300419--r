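#' Specification for the latent-structure synthetic generator
#'
#' Collects and validates the parameters of the seeded generator used to
#' exercise the modelling pipeline without proprietary descriptor software.
#' Defaults emulate the scale of the real study: about eighty compounds, a
#' few hundred descriptors, two latent factors driving a handful of
#' informative descriptors, and response noise of 0.3 log10 units.
#'
#' @param n Number of compounds (default 80).
#' @param p Number of descriptors (default 300).
#' @param k Latent components, `1 <= k < n` (default 2).
#' @param informative Number of descriptors loading on the latent factors
#'   (default 5).
#' @param loading Magnitude scale of the informative loadings (default 1).
#' @param x_noise_sd Descriptor noise standard deviation (default 0.3).
#' @param noise_sd Response noise standard deviation, log10 units
#'   (default 0.3).
#' @param skew_fraction Fraction of the uninformative descriptors drawn as
#'   exponentiated normals (heavily right-skewed) to exercise the cube-root
#'   transform and the normality screen (default 0.1).
#' @param outliers Number of rows displaced orthogonally to the latent plane
#'   (default 0).
#' @param outlier_magnitude Displacement in pooled residual standard
#'   deviations (default 10).
#' @param test_shift Mean response offset (log10 units) applied to a
#'   discovery-like subset; 0 disables the subset (default 0).
#' @param shift_fraction Fraction of compounds in the shifted subset
#'   (default 0.25).
#' @param seed Integer seed; identical spec + seed reproduce the dataset
#'   exactly (Mersenne-Twister, R default generator).
#' @return A validated `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 80, p = 300, k = 2, informative = 5,
                           loading = 1, x_noise_sd = 0.3, noise_sd = 0.3,
                           skew_fraction = 0.1, outliers = 0,
                           outlier_magnitude = 10, test_shift = 0,
                           shift_fraction = 0.25, seed = 1) {
  spec <- list(n = n, p = p, k = k, informative = informative,
               loading = loading, x_noise_sd = x_noise_sd, noise_sd = noise_sd,
               skew_fraction = skew_fraction, outliers = outliers,
               outlier_magnitude = outlier_magnitude, test_shift = test_shift,
               shift_fraction = shift_fraction, seed = as.integer(seed))
  if (!(n > k && k >= 1)) abort("need n > k >= 1")
  if (p < informative) abort("p must be at least the informative count")
  if (noise_sd < 0 || x_noise_sd < 0) abort("noise standard deviations must be >= 0")
  if (skew_fraction < 0 || skew_fraction > 1) abort("skew_fraction in [0, 1]")
  if (outliers > n) abort("more outliers than rows")
  structure(spec, class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec>", x$n, "x", x$p, "with", x$k, "latent factors,",
      x$informative, "informative descriptors, noise sd", x$noise_sd,
      "(seed", paste0(x$seed, ")\n"))
  invisible(x)
}

#' Generate a descriptor/response dataset with known latent structure
#'
#' Draws latent scores `T` (n x k, standard normal), sparse loadings `P`
#' (only the planted informative descriptors load on the factors), descriptor
#' noise `E` and builds `X = T P' + E`; the response is `y = T q + f` with
#' `q` fixed at `seq(1, 0.5, length.out = k)` times the loading scale and `f`
#' normal with the specified noise. The planted loading directions are spread
#' within a 45-degree cone around the response-weight direction, so each
#' planted descriptor is individually response-relevant and the planted
#' support is recoverable by a Q2-guided selection. A fraction of the uninformative
#' descriptors is replaced by exponentiated normals, planted outliers are
#' displaced orthogonally to the latent plane, and an optional discovery-like
#' subset (the last rows) has its response shifted. Everything is a pure
#' function of the spec and its seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `x` (descriptor tibble with `name` column), `y`
#'   (named response vector) and `truth` (latent scores, loadings, response
#'   weights, informative/skewed descriptor names, outlier and shifted row
#'   names).
#' @export
generate_latent_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed, kind = "Mersenne-Twister")
  n <- spec$n; p <- spec$p; k <- spec$k
  names_c <- sprintf("CMP%03d", seq_len(n))
  names_d <- sprintf("X%03d", seq_len(p))
  informative <- names_d[seq_len(spec$informative)]
  Tm <- matrix(rnorm(n * k), n, k, dimnames = list(names_c, NULL))
  P <- matrix(0, p, k, dimnames = list(names_d, NULL))
  q <- spec$loading * seq(1, 0.5, length.out = k)
  if (spec$informative > 0) {
    # planted loadings are spread within a 45-degree cone around the
    # response-weight direction: "informative" means response-relevant, so
    # every planted descriptor must carry predictive information on its own.
    # Directions far from the cone (in particular, orthogonal to q) belong
    # to the background by definition - a Q2-guided selection correctly
    # discards them, which would make support recovery meaningless.
    m_inf <- spec$informative
    mags <- spec$loading * runif(m_inf, 0.7, 1)
    qdir <- q / sqrt(sum(q^2))
    dirs <- if (k == 1) {
      matrix(sample(c(-1, 1), m_inf, replace = TRUE), ncol = 1)
    } else {
      theta <- if (m_inf == 1) 0 else seq(-pi / 4, pi / 4, length.out = m_inf)
      t(vapply(seq_len(m_inf), function(j) {
        u <- rnorm(k)
        u <- u - sum(u * qdir) * qdir
        if (sqrt(sum(u^2)) < 1e-12) u <- c(-qdir[2], qdir[1], rep(0, k - 2))
        u <- u / sqrt(sum(u^2))
        if (k == 2 && u[1] * qdir[2] - u[2] * qdir[1] > 0) u <- -u
        cos(theta[j]) * qdir + sin(theta[j]) * u
      }, numeric(k)))
    }
    P[informative, ] <- mags * dirs
  }
  X <- Tm %*% t(P) + matrix(rnorm(n * p, 0, spec$x_noise_sd), n, p)
  dimnames(X) <- list(names_c, names_d)
  n_skew <- round(spec$skew_fraction * (p - spec$informative))
  skewed <- character(0)
  if (n_skew > 0) {
    skewed <- sample(setdiff(names_d, informative), n_skew)
    # sd 3 keeps these heavily skewed even after a cube-root transform and at
    # the small sample sizes typical of solubility datasets
    X[, skewed] <- matrix(exp(rnorm(n * n_skew, 0, 3)), n, n_skew)
  }
  y <- drop(Tm %*% q) + rnorm(n, 0, spec$noise_sd)
  shifted <- character(0)
  if (spec$test_shift != 0 && spec$shift_fraction > 0) {
    n_shift <- ceiling(spec$shift_fraction * n)
    shifted <- tail(names_c, n_shift)
    y[names_c %in% shifted] <- y[names_c %in% shifted] + spec$test_shift
  }
  outlier_rows <- character(0)
  if (spec$outliers > 0) {
    outlier_rows <- tail(setdiff(names_c, shifted), spec$outliers)
    for (nm in outlier_rows) {
      X <- as_descriptor_matrix(
        plant_outlier(X, nm, spec$outlier_magnitude, P)
      )
    }
  }
  names(y) <- names_c
  list(
    x = descriptor_tbl(X),
    y = y,
    truth = list(scores = Tm, loadings = P, q = q,
                 informative = informative, skewed = skewed,
                 outliers = outlier_rows, shifted = shifted,
                 noise_sd = spec$noise_sd)
  )
}

#' Displace one row orthogonally to a latent plane
#'
#' Moves a single observation out of the column space of the supplied
#' loadings by `magnitude` pooled residual standard deviations (scaled by
#' `sqrt(p - k)` so the resulting DModX of the row is about `magnitude`).
#' The displacement direction is the deterministic projection of the
#' all-ones vector onto the residual space; other rows are untouched.
#'
#' @param x Descriptor table or matrix.
#' @param row Row name or index to displace.
#' @param magnitude Displacement in pooled residual standard deviations;
#'   0 returns the input unchanged.
#' @param loadings p x k loading matrix defining the latent plane (e.g.
#'   `truth$loadings` from [generate_latent_dataset()], or PCA loadings).
#' @return The modified descriptor tibble.
#' @export
plant_outlier <- function(x, row, magnitude, loadings) {
  m <- as_descriptor_matrix(x)
  if (is.character(row)) {
    if (!row %in% rownames(m)) abort(paste0("row '", row, "' not found"))
  } else {
    if (row < 1 || row > nrow(m)) abort("row index out of range")
    row <- rownames(m)[row]
  }
  if (magnitude == 0) return(descriptor_tbl(m))
  k <- ncol(loadings)
  p <- ncol(m)
  if (p <= k) abort("no residual space to displace into (p <= k)")
  qrP <- qr(loadings)
  v <- rep(1, p)
  v_orth <- v - qr.fitted(qrP, v)
  if (sqrt(sum(v_orth^2)) < 1e-10) {
    v <- c(1, rep(0, p - 1))
    v_orth <- v - qr.fitted(qrP, v)
  }
  v_unit <- v_orth / sqrt(sum(v_orth^2))
  centers <- colMeans(m)
  mc <- sweep(m, 2, centers, "-")
  proj <- qr.fitted(qrP, t(mc))
  E <- mc - t(proj)
  s0 <- sqrt(sum(E^2) / ((nrow(m) - k - 1) * (p - k)))
  m[row, ] <- m[row, ] + magnitude * s0 * sqrt(p - k) * v_unit
  descriptor_tbl(m)
}

#' Generate a dataset shaped like the bundled solubility table
#'
#' Draws correlated log10 molar solubilities for the three media from a
#' trivariate normal whose pairwise squared correlations default to the ones
#' observed between real media (buffer-FaSSIF 0.61, buffer-HIF 0.62,
#' FaSSIF-HIF 0.78), applies per-medium missingness matching the real table
#' (all compounds have FaSSIF; roughly 73% have buffer and 56% HIF values),
#' and populates lipophilicity, melting point and the other physicochemical
#' columns. Calculated logD is coupled to the FaSSIF-buffer solubilization
#' gap so lipophilicity strata behave qualitatively like real data. Values
#' are clamped to the [-12, 0] solubility invariant.
#'
#' @param n Number of compounds (default 86).
#' @param r2_pf,r2_ph,r2_fh Target squared correlations between media.
#' @param miss_phb,miss_hif Fractions of compounds lacking buffer / HIF
#'   measurements.
#' @param test_shift Optional mean log10 shift of the `Te` subset's
#'   solubilities (discovery-like sets are less soluble); default 0.
#' @param seed Integer seed.
#' @return A validated solubility dataset tibble.
#' @export
generate_tablelike_dataset <- function(n = 86, r2_pf = 0.61, r2_ph = 0.62,
                                       r2_fh = 0.78, miss_phb = 23 / 86,
                                       miss_hif = 38 / 86, test_shift = 0,
                                       seed = 1) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  rho <- diag(3)
  rho[1, 2] <- rho[2, 1] <- sqrt(r2_pf)
  rho[1, 3] <- rho[3, 1] <- sqrt(r2_ph)
  rho[2, 3] <- rho[3, 2] <- sqrt(r2_fh)
  ev <- eigen(rho, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 3)
  z <- matrix(rnorm(n * 3), n, 3) %*% t(L)
  mu <- c(-4.4, -3.9, -4.0)
  sdv <- c(1.2, 0.75, 0.95)
  sol <- sweep(sweep(z, 2, sdv, "*"), 2, mu, "+")
  sol <- pmin(pmax(sol, -12), 0)
  logd <- pmin(pmax(2 + 1.5 * (sol[, 2] - sol[, 1]) + rnorm(n, 0, 1), -0.2), 10)
  ds <- tibble::tibble(
    name = sprintf("CMP%03d", seq_len(n)),
    set = NA_character_,
    mw = round(exp(rnorm(n, log(400), 0.3)), 1),
    logd65 = round(logd, 1),
    psa = round(runif(n, 3, 300), 1),
    rotb = stats::rpois(n, 5),
    logs_phb = round(sol[, 1], 2),
    logs_fassif = round(sol[, 2], 2),
    logs_hif = round(sol[, 3], 2),
    tm_c = round(pmin(pmax(rnorm(n, 165, 55), 40), 360), 1)
  )
  split <- sorted_thirds_split(ds, "fassif")
  ds$set <- ifelse(ds$name %in% split$test, "Te", "Tr")
  if (test_shift != 0) {
    te <- ds$set == "Te"
    for (col in c("logs_phb", "logs_fassif", "logs_hif")) {
      ds[[col]][te] <- pmin(pmax(ds[[col]][te] + test_shift, -12), 0)
    }
  }
  ds$logs_phb[sample.int(n, round(miss_phb * n))] <- NA_real_
  ds$logs_hif[sample.int(n, round(miss_hif * n))] <- NA_real_
  validate_solubility_data(ds)
}
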