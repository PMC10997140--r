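# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

## default 7-bundle phantom at reduced streamline count (30 per bundle)
test_phantom <- function() {
  cached("phantom30", generate_phantom(
    phantom_spec(bundles = default_bundles(n_streamlines = 30), seed = 11),
    check = FALSE))
}

## phantom whose truth count is exactly 100, for the LiFE recovery checks
life_phantom <- function() {
  cached("phantom100", {
    bs <- default_bundles(n_streamlines = 15)
    for (q in 3:7) bs[[q]]$n_streamlines <- 14L
    generate_phantom(phantom_spec(bundles = bs, seed = 7), check = FALSE)
  })
}

## smooth random polyline: a start point plus cumulated random steps
random_streamline <- function(n = 8, scale = 10, centre = c(0, 0, 0)) {
  steps <- matrix(rnorm(n * 3, sd = 2 * scale / n), n, 3)
  steps[1, ] <- rnorm(3, sd = scale / 2)
  sweep(apply(steps, 2, cumsum), 2, centre, `+`)
}

## small random mask on a grid with a random (axis-aligned) affine
random_mask <- function(shape = c(8, 8, 8), n_true = 6, voxel = 2,
                        origin = -8) {
  aff <- diag(c(rep(voxel, 3), 1)); aff[1:3, 4] <- origin
  m <- array(FALSE, dim = shape)
  m[sample(prod(shape), n_true)] <- TRUE
  binary_mask(m, aff, name = "rand", hemisphere = "auto")
}
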