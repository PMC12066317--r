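# Shared fixtures (memoised: several files reuse the same cohorts) and
# independent oracles used against the package implementations.

.fixture_cache <- new.env(parent = emptyenv())

cached_cohort <- function(n, scenario, seed, noise_sd = NULL,
                          n_fibers_per_bundle = 60) {
  key <- paste(n, scenario, seed, noise_sd %||% "def", n_fibers_per_bundle,
               sep = "_")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_cohort(
      n, scenario, seed = seed, noise_sd = noise_sd,
      n_fibers_per_bundle = n_fibers_per_bundle)
  .fixture_cache[[key]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive sign-enumeration oracle for the two-sided one-sample
# signed-rank test: p = P(|W' - mu| >= |w - mu|) over all 2^n sign flips
enum_signed_rank_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  if (n == 0) return(1)
  r <- rank(abs(x))
  w <- sum(r[x > 0])
  mu <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  mean(abs(ws - mu) >= abs(w - mu) - 1e-12)
}

# direct pooled-variance two-sample t oracle
pooled_t_oracle <- function(a, b) {
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

# minimal single-electrode frame for unit tests, contacts along +z
toy_electrode <- function(base = c(0, 0, 0), active = 1L, amplitude = 2.5,
                          patient = "P01", hemisphere = "left",
                          spacing = 2) {
  cc <- t(vapply(0:3, function(k) base + c(0, 0, k * spacing), numeric(3)))
  df <- data.frame(patient_id = patient, hemisphere = hemisphere,
                   stringsAsFactors = FALSE)
  df[dbsmap:::contact_cols] <- as.list(as.vector(t(cc)))
  df$active_contact <- as.integer(active)
  df$amplitude_v <- amplitude
  df$frequency_hz <- 130
  df$pulse_width_us <- 60
  df$mode <- "monopolar"
  df
}

# small isotropic grid centered on the origin
toy_grid <- function(n = 33, voxel = 0.5) {
  aff <- diag(c(voxel, voxel, voxel, 1))
  aff[1:3, 4] <- -voxel * (n - 1) / 2
  image_volume(array(0, c(n, n, n)), aff)
}
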