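# Shared fixtures, built in code at test time.

sine_trace <- function(freq_hz, duration_s, fs_hz = 10000, amp = 1,
                       phase = 0) {
  t <- (seq_len(round(duration_s * fs_hz)) - 1) / fs_hz
  lfp_trace(amp * sin(2 * pi * freq_hz * t + phase), fs_hz)
}

# Brute-force connected-component count by recursive region growing on a
# pixel set representation -- independent of the package's flood fill.
brute_component_count <- function(mask, connectivity = 8L) {
  coords <- which(mask, arr.ind = TRUE)
  if (nrow(coords) == 0L) return(0L)
  key <- paste(coords[, 1], coords[, 2])
  unvisited <- stats::setNames(rep(TRUE, nrow(coords)), key)
  neigh <- function(r, c) {
    if (connectivity == 8L) {
      d <- expand.grid(dr = -1:1, dc = -1:1)
      d <- d[!(d$dr == 0 & d$dc == 0), ]
    } else {
      d <- data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
    }
    paste(r + d$dr, c + d$dc)
  }
  comps <- 0L
  for (i in seq_len(nrow(coords))) {
    k <- key[i]
    if (!unvisited[k]) next
    comps <- comps + 1L
    frontier <- k
    unvisited[k] <- FALSE
    while (length(frontier)) {
      nxt <- character(0)
      for (f in frontier) {
        rc <- as.integer(strsplit(f, " ")[[1]])
        for (nb in neigh(rc[1], rc[2])) {
          if (!is.na(unvisited[nb]) && unvisited[nb]) {
            unvisited[nb] <- FALSE
            nxt <- c(nxt, nb)
          }
        }
      }
      frontier <- nxt
    }
  }
  comps
}
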