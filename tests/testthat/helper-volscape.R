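# Shared fixtures, built in code. The default phantom is used where the
# CP/RP geometry matters; `tiny_grid()` makes small seeded random maps for
# pure volume-algebra tests.

tiny_grid <- function(n = 16, seed = 1, voxel = 4) {
  set.seed(seed)
  voxel_grid(array(stats::rnorm(n^3), dim = c(n, n, n)), voxel_size = voxel)
}

default_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- phantom_spec()
      cache <<- list(spec = spec, masks = phantom_masks(spec),
                     ref = render_phantom(spec, 0))
    }
    cache
  }
})

# independent 2D inner-angle oracle (law-of-cosines on the plane)
hexagon_angles_2d <- function(uv) {
  n <- nrow(uv)
  sapply(seq_len(n), function(i) {
    p <- uv[i, ]
    a <- uv[if (i == 1) n else i - 1, ]
    b <- uv[if (i == n) 1 else i + 1, ]
    la <- sqrt(sum((a - p)^2)); lb <- sqrt(sum((b - p)^2))
    lc <- sqrt(sum((a - b)^2))
    acos((la^2 + lb^2 - lc^2) / (2 * la * lb)) * 180 / pi
  })
}

# a 15-residue synthetic chain: three 5-residue segments with controllable
# per-segment B-factors; full backbone + 2 side-chain atoms per residue
# (CG, CD), except glycine at position 8 (no CB/side chain)
synthetic_chain <- function(b_by_segment = c(50, 130, 200)) {
  rows <- list()
  for (r in 1:15) {
    seg <- (r - 1) %/% 5 + 1
    is_gly <- r == 8
    atoms <- if (is_gly) c("N", "CA", "C", "O")
             else c("N", "CA", "C", "O", "CB", "CG", "CD")
    resname <- if (is_gly) "GLY" else "LEU"
    for (a in atoms) {
      rows[[length(rows) + 1]] <- data.frame(
        chain = "A", resno = r, resname = resname, atom = a,
        x = r * 3.8 + stats::runif(1, 0, 0.1), y = match(a, atoms) * 1.1,
        z = 0, b = b_by_segment[seg]
      )
    }
  }
  atomic_model(do.call(rbind, rows))
}
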