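# Independent oracles used across the suite. Each is a deliberately
# brute-force implementation kept free of the code paths it checks.

# Exhaustive global-alignment score: enumerate every monotone alignment
# path, scoring affine gaps as open + extend * length.
align_score_oracle <- function(q, r, submat, gap_open = 10, gap_extend = 1) {
  qc <- strsplit(q, "")[[1L]]
  rc <- strsplit(r, "")[[1L]]
  nq <- length(qc); nr <- length(rc)
  best <- -Inf
  rec <- function(i, j, last, sc) {
    if (i > nq && j > nr) {
      if (sc > best) best <<- sc
      return(invisible(NULL))
    }
    if (i <= nq && j <= nr)
      rec(i + 1L, j + 1L, "M", sc + submat[qc[i], rc[j]])
    if (i <= nq)
      rec(i + 1L, j, "I",
          sc - gap_extend - if (identical(last, "I")) 0 else gap_open)
    if (j <= nr)
      rec(i, j + 1L, "D",
          sc - gap_extend - if (identical(last, "D")) 0 else gap_open)
    invisible(NULL)
  }
  rec(1L, 1L, "start", 0)
  best
}

# Sort-and-interpolate percentile (the linear-interpolation convention),
# written from the definition rather than via quantile().
percentile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Brute-force Michaelis-Menten fit: SSR minimum over a Km x Vmax grid.
mm_grid_oracle <- function(s, v, km_range, vmax_range, n = 200) {
  kms <- seq(km_range[1L], km_range[2L], length.out = n)
  vmaxs <- seq(vmax_range[1L], vmax_range[2L], length.out = n)
  best <- c(km = NA_real_, vmax = NA_real_, ssr = Inf)
  for (km in kms) {
    pred_unit <- s / (km + s)
    for (vm in vmaxs) {
      ssr <- sum((v - vm * pred_unit)^2)
      if (ssr < best[["ssr"]]) best <- c(km = km, vmax = vm, ssr = ssr)
    }
  }
  best
}

blosum62_sub <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

# all sequences over `alphabet` with lengths in `lens`
all_seqs <- function(alphabet, lens) {
  unlist(lapply(lens, function(L) {
    g <- do.call(expand.grid, rep(list(alphabet), L))
    apply(g, 1L, paste, collapse = "")
  }))
}
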