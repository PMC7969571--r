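# Internal numerical helpers shared across modules.

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic operations in the
# package route their randomness through this.
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("seed must be a single integer")
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(as.integer(seed))
    force(expr)
}

# Round half away from zero at `digits` decimal places (printed-figure
# convention; base::round is half-to-even).
roundHalfUp <- function(x, digits = 0) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

# Bilinear resample of matrix `z` (rows = y, cols = x) whose pixel centers
# sit at (i + 0.5) * spacing, onto query center coordinates `xq`, `yq`
# (world mm). Queries outside the source extent clamp to the border value.
bilinearResample <- function(z, spacingRow, spacingCol, yq, xq) {
    ys <- (seq_len(nrow(z)) - 0.5) * spacingRow
    xs <- (seq_len(ncol(z)) - 0.5) * spacingCol
    yq <- pmin(pmax(yq, ys[1]), ys[length(ys)])
    xq <- pmin(pmax(xq, xs[1]), xs[length(xs)])
    if (length(ys) == 1L && length(xs) == 1L)
        return(matrix(z[1, 1], length(yq), length(xq)))
    # separable linear interpolation
    iy <- findInterval(yq, ys, rightmost.closed = TRUE)
    iy <- pmin(pmax(iy, 1L), length(ys) - 1L)
    wy <- (yq - ys[iy]) / (ys[iy + 1L] - ys[iy])
    ix <- findInterval(xq, xs, rightmost.closed = TRUE)
    ix <- pmin(pmax(ix, 1L), length(xs) - 1L)
    wx <- (xq - xs[ix]) / (xs[ix + 1L] - xs[ix])
    if (length(ys) == 1L) { iy <- rep(1L, length(yq)); wy <- rep(0, length(yq)) }
    if (length(xs) == 1L) { ix <- rep(1L, length(xq)); wx <- rep(0, length(xq)) }
    z11 <- z[iy, ix, drop = FALSE]
    z21 <- z[iy + (nrow(z) > 1L), ix, drop = FALSE]
    z12 <- z[iy, ix + (ncol(z) > 1L), drop = FALSE]
    z22 <- z[iy + (nrow(z) > 1L), ix + (ncol(z) > 1L), drop = FALSE]
    WY <- matrix(wy, length(yq), length(xq))
    WX <- matrix(wx, length(yq), length(xq), byrow = TRUE)
    z11 * (1 - WY) * (1 - WX) + z21 * WY * (1 - WX) +
        z12 * (1 - WY) * WX + z22 * WY * WX
}

# Nearest-neighbour resize of a matrix to nrowOut x ncolOut (used for label
# maps, where interpolation must not invent classes).
nnResize <- function(m, nrowOut, ncolOut) {
    ri <- pmin(nrow(m), pmax(1L, ceiling((seq_len(nrowOut) - 0.5) *
                                         nrow(m) / nrowOut)))
    ci <- pmin(ncol(m), pmax(1L, ceiling((seq_len(ncolOut) - 0.5) *
                                         ncol(m) / ncolOut)))
    m[ri, ci, drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
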