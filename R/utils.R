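## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Smallest power of 2 >= n (n >= 1).
nextPow2 <- function(n) {
  stopifnot(n >= 1)
  as.integer(2^ceiling(log2(n) - 1e-12))
}

## Round-half-up to nearest integer (the paper is silent on the rounding
## rule for sample remapping; half-up is declared and documented).
roundHalfUp <- function(x) floor(x + 0.5)

## Merge a 2-column matrix of half-open [start, end) intervals: sort,
## coalesce overlapping and adjacent ([a,b) + [b,c) -> [a,c)).
mergeIntervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) {
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  iv <- iv[order(iv[, 1L], iv[, 2L]), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  if (nrow(iv) > 1L) for (i in 2L:nrow(iv)) {
    k <- nrow(out)
    if (iv[i, 1L] <= out[k, 2L]) {
      out[k, 2L] <- max(out[k, 2L], iv[i, 2L])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  colnames(out) <- c("start", "end")
  out
}

## Complement of merged mask intervals within [0, n): the usable gaps.
intervalGaps <- function(iv, n) {
  if (is.null(iv) || nrow(iv) == 0L) {
    return(matrix(c(0, n), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  starts <- c(0, iv[, 2L])
  ends <- c(iv[, 1L], n)
  keep <- ends > starts
  matrix(c(starts[keep], ends[keep]), ncol = 2L,
         dimnames = list(NULL, c("start", "end")))
}

## Empty event table with the canonical columns.
emptyEvents <- function() {
  data.frame(label = character(0), period = integer(0), sample = numeric(0),
             applied_offset_samples = numeric(0), stringsAsFactors = FALSE)
}

nowStamp <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
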