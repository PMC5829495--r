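# internal helpers shared across modules

# evaluate `code` under a temporary RNG state seeded with `seed`
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derived sub-seed kept inside 32-bit integer range
subSeed <- function(seed, offset) {
  as.integer((as.double(seed) + as.double(offset)) %% 2147483629)
}

# 1-based inclusive row span (top, bottom) of the neurite at its base
# diameter; varicosities widen this locally
neuriteRowSpan <- function(phantom, extraPx = 0) {
  d <- phantom@diameterPx
  top0 <- phantom@axisRow - (d - 1L) %/% 2L        # 0-based top row
  extraHalf <- as.integer(round(extraPx / 2))
  c(top0 + 1L - extraHalf, top0 + d + extraHalf)   # 1-based inclusive
}

# 1-based inclusive row span of the bundle (centred within the neurite)
bundleRowSpan <- function(phantom) {
  d <- phantom@diameterPx
  w <- phantom@bundleWidthPx
  top0 <- phantom@axisRow - (d - 1L) %/% 2L
  btop0 <- top0 + (d - w) %/% 2L
  c(btop0 + 1L, btop0 + w)
}

# extra neurite diameter contributed by varicosities at 0-based column x
varicosityExtra <- function(phantom, x) {
  v <- phantom@varicosities
  if (!nrow(v)) return(rep(0, length(x)))
  extra <- rep(0, length(x))
  for (i in seq_len(nrow(v))) {
    sigma <- max(4, v[i, 2L])                      # longitudinal spread
    extra <- pmax(extra, v[i, 2L] * exp(-((x - v[i, 1L])^2) / (2 * sigma^2)))
  }
  extra
}

# overlap weights of unit-width pixel rows (bundle-local) with the five
# equal-width transverse bins; rows x 5 matrix, rows sum to 1
binRowWeights <- function(widthPx) {
  bounds <- seq(0, widthPx, length.out = 6L)
  w <- matrix(0, nrow = widthPx, ncol = 5L)
  for (r in seq_len(widthPx)) {
    lo <- r - 1
    hi <- r
    for (b in 1:5) {
      ov <- max(0, min(hi, bounds[b + 1L]) - max(lo, bounds[b]))
      w[r, b] <- ov
    }
  }
  w
}

binNames <- c("bin_edge_l", "bin_int_l", "bin_center", "bin_int_r", "bin_edge_r")
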