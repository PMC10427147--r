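# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

fix_patch <- function() fixture("patch", function() make_flat_patch(6000, "left", seed = 1))

fix_canon <- function() fixture("canon", function() canonical_fields(fix_patch()))

fix_small_patch <- function() fixture("small_patch", function() make_flat_patch(800, "left", seed = 2))

fix_small_canon <- function() fixture("small_canon", function() canonical_fields(fix_small_patch()))

# Random discrete map on shared vertex ids (for Jaccard oracles).
random_discrete <- function(n, seed, levels = c("0", "90", "270", "360")) {
  withr::with_seed(seed, {
    structure(
      list(
        labels = sample(levels, n, replace = TRUE),
        vertex_id = seq_len(n) - 1L,
        levels = levels,
        scope = "test"
      ),
      class = "discrete_map"
    )
  })
}

# Set-arithmetic Jaccard oracle, independent of the incidence-matrix path.
jaccard_oracle <- function(ref, oth) {
  num <- 0
  den <- 0
  for (L in ref$levels) {
    ids_ref <- ref$vertex_id[ref$labels == L]
    ids_oth <- oth$vertex_id[oth$labels == L]
    w <- length(ids_ref)
    if (w == 0) next
    u <- length(union(ids_ref, ids_oth))
    j <- length(intersect(ids_ref, ids_oth)) / u
    num <- num + w * j
    den <- den + w
  }
  num / den
}
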