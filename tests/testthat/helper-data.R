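# shared fixtures, built in code

toy_dataset <- function() {
  tibble::tibble(
    name = c("alpha", "beta", "gamma"),
    set = c("Tr", "Te", "Tr"),
    mw = c(300, 400, 500),
    logd65 = c(1.5, 2.5, 3.0),
    psa = c(50, 80, 110),
    rotb = c(2L, 5L, 8L),
    logs_phb = c(-3.0, -4.5, NA),
    logs_fassif = c(-2.8, -4.0, -5.0),
    logs_hif = c(-3.1, NA, -4.8),
    tm_c = c(150, 210, NA)
  )
}

# small latent dataset used across latent/model-building tests
tiny_latent <- function(seed = 11, n = 40, p = 12, k = 2, informative = 4,
                        noise_sd = 0.2, skew_fraction = 0, ...) {
  generate_latent_dataset(synthetic_spec(
    n = n, p = p, k = k, informative = informative, noise_sd = noise_sd,
    skew_fraction = skew_fraction, seed = seed, ...))
}

random_matrix <- function(n, p, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("r%02d", seq_len(n)),
                              sprintf("c%02d", seq_len(p))))
  m
}

as_matrix_helper <- function(tbl) {
  m <- as.matrix(tbl[setdiff(names(tbl), "name")])
  rownames(m) <- tbl$name
  m
}

as_descriptor_matrix_helper <- function(tbl) as_matrix_helper(tbl)
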