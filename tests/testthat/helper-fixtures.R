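# Shared fixtures. Heavy objects are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

random_ts <- function(t, v, seed, region_tag = "seed") {
  set.seed(seed)
  timeseries_matrix(matrix(rnorm(t * v), t, v), region_tag = region_tag)
}

# small cohort for unit tests: ~100 seed voxels, 256 target voxels, t = 60
small_synth_config <- function(n_subjects = 4L, ...) {
  defaults <- list(n_subjects = n_subjects, seed_grid = c(6L, 6L, 6L),
                   target_grid = c(8L, 8L, 4L), t = 60L, master_seed = 2024L)
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

small_cohort <- function() {
  cached("small_cohort", generate_cohort(small_synth_config()))
}

# full-scale cohort at the stated defaults (t = 120, m ~ 250, n = 600,
# 20 subjects) for the acceptance criteria
default_cohort <- function() {
  cached("default_cohort", generate_cohort(synth_config()))
}

# per-subject similarity matrices for all four variants (cosine measure)
cohort_similarities <- function(cohort, key) {
  cached(paste0("sims_", key), {
    lapply(cohort$subjects, function(s) {
      sapply(c("original", "rescaled", "voxelwise", "within_seed"),
             function(v) {
               build_similarity(s$seed, s$target, v,
                                measure = if (v == "within_seed") NULL
                                          else "cosine")
             }, simplify = FALSE)
    })
  })
}

random_orthogonal <- function(n, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(n * n), n, n)))
}
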