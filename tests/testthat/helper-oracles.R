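# Independent oracles and fixture builders used across the test files.

# Stack-based flood fill — an implementation of connected-component labeling
# deliberately independent of the package's union-find path.
flood_fill_components <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  offsets <- if (connectivity == 4L) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else {
    expand.grid(dr = -1L:1L, dc = -1L:1L) |>
      (\(g) g[!(g$dr == 0 & g$dc == 0), ])() |>
      (\(g) lapply(seq_len(nrow(g)), function(i) c(g$dr[i], g$dc[i])))()
  }
  label <- matrix(0L, h, w)
  n <- 0L
  for (sr in seq_len(h)) {
    for (sc in seq_len(w)) {
      if (mask[sr, sc] == 1L && label[sr, sc] == 0L) {
        n <- n + 1L
        stack <- list(c(sr, sc))
        label[sr, sc] <- n
        while (length(stack)) {
          p <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          for (o in offsets) {
            r <- p[1L] + o[1L]; c <- p[2L] + o[2L]
            if (r >= 1L && r <= h && c >= 1L && c <= w &&
                mask[r, c] == 1L && label[r, c] == 0L) {
              label[r, c] <- n
              stack[[length(stack) + 1L]] <- c(r, c)
            }
          }
        }
      }
    }
  }
  list(label_map = label, n_components = n)
}

# Two labelings partition the foreground identically iff pixels share a
# component in one labeling exactly when they share one in the other.
same_partition <- function(lab1, lab2) {
  if (max(lab1) != max(lab2)) return(FALSE)
  f <- lab1 > 0
  if (!identical(f, lab2 > 0)) return(FALSE)
  key1 <- lab1[f]; key2 <- lab2[f]
  length(unique(paste(key1, key2))) == max(lab1)
}

random_mask <- function(h, w, p = 0.35) {
  matrix(as.integer(runif(h * w) < p), h, w)
}

# Minimal instance: image intensity follows the masks so the phantom-free
# tests stay fast.
make_instance <- function(soma, vessel, id = "t1", image = NULL) {
  if (is.null(image)) {
    image <- matrix(128L, nrow(soma), ncol(soma))
    image[soma == 1L] <- 70L
    image[vessel == 1L] <- 225L
  }
  annotated_instance(image, list(soma = soma, vessel = vessel), id)
}

# a small blob mask with a given top-left corner and size
blob <- function(h, w, r0, c0, nr, nc) {
  m <- matrix(0L, h, w)
  m[r0:(r0 + nr - 1L), c0:(c0 + nc - 1L)] <- 1L
  m
}
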