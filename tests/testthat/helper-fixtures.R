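# Shared fixtures: built once per test run, in code, no stored data.

# a clean synthetic bundle plus its map and the extracted Bundle
fixture_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b <- build_bundle(receptor_id = "syn", entry_id = "SYN1")
      cache <<- list(chain = b$chain, map = b$map,
                     bundle = extract_bundle(b$chain, b$map))
    }
    cache
  }
})

# a bundle with a distinct sequence (fixed, not random)
fixture_bundle2 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      seq2 <- paste(rep(c("G", "L", "S", "V"), 50), collapse = "")
      b <- build_bundle(receptor_id = "syn2", sequence = seq2,
                        entry_id = "SYN2")
      cache <<- list(chain = b$chain, map = b$map,
                     bundle = extract_bundle(b$chain, b$map))
    }
    cache
  }
})

# random proper rotation from a fixed-seed stream
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

rigidly_move_bundle <- function(bundle, R, t) {
  out <- bundle
  out$xyz <- sweep(bundle$xyz %*% t(R), 2, t, "+")
  dimnames(out$xyz) <- dimnames(bundle$xyz)
  out
}
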