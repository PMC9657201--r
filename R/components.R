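# Connected-component labeling on binary masks with 8-connectivity,
# implemented as a run-length union-find: foreground runs are extracted per
# row in one flattened diff pass, and runs in adjacent rows are merged when
# their column ranges overlap or touch diagonally. Masks whose rows carry a
# single run each (every compliant silhouette) take a fully vectorized
# chain-labeling path.

# Foreground runs per row: data.frame(row, start, end), ordered by row.
mask_runs <- function(mask) {
  w <- ncol(mask)
  idx <- which(as.vector(t(mask)))  # image row-major positions
  if (!length(idx)) return(data.frame(row = integer(0), start = integer(0),
                                      end = integer(0)))
  brk <- which(diff(idx) > 1L)
  s <- idx[c(1L, brk + 1L)]
  e <- idx[c(brk, length(idx))]
  rs <- (s - 1L) %/% w
  re <- (e - 1L) %/% w
  cross <- which(re > rs)
  if (length(cross)) {
    # split runs that wrap across row boundaries into per-row pieces
    ks <- integer(0); ke <- integer(0)
    for (i in cross) {
      for (r in rs[i]:re[i]) {
        ks <- c(ks, max(s[i], r * w + 1L))
        ke <- c(ke, min(e[i], (r + 1L) * w))
      }
    }
    s <- c(s[-cross], ks); e <- c(e[-cross], ke)
    o <- order(s)
    s <- s[o]; e <- e[o]
    rs <- (s - 1L) %/% w; re <- (e - 1L) %/% w
  }
  data.frame(row = rs + 1L, start = s - rs * w, end = e - rs * w)
}

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# Component id per run (1-based, in order of first appearance).
run_labels <- function(runs) {
  nr <- nrow(runs)
  if (nr == 0L) return(integer(0))
  rows <- runs$row
  if (!anyDuplicated(rows)) {
    # one run per row: components are maximal chains of touching runs
    link <- rows[-1L] == rows[-nr] + 1L &
      runs$start[-1L] <= runs$end[-nr] + 1L &
      runs$end[-1L] >= runs$start[-nr] - 1L
    return(cumsum(c(TRUE, !link)))
  }
  parent <- seq_len(nr)
  prev_idx <- integer(0)
  prev_row <- -1L
  i <- 1L
  while (i <= nr) {
    r <- rows[i]
    j <- i
    while (j < nr && rows[j + 1L] == r) j <- j + 1L
    cur <- i:j
    if (r == prev_row + 1L && length(prev_idx)) {
      for (a in cur) {
        sa <- runs$start[a] - 1L; ea <- runs$end[a] + 1L
        for (b in prev_idx) {
          if (runs$start[b] <= ea && runs$end[b] >= sa) {
            ra <- uf_find(parent, a); rb <- uf_find(parent, b)
            if (ra != rb) parent[rb] <- ra
          }
        }
      }
    }
    prev_idx <- cur
    prev_row <- r
    i <- j + 1L
  }
  root <- vapply(seq_len(nr), function(k) uf_find(parent, k), integer(1))
  match(root, unique(root))
}

runs_to_mask <- function(runs, keep, nrow, ncol) {
  out <- matrix(FALSE, nrow, ncol)
  for (k in keep) {
    out[cbind(runs$row[k], runs$start[k]:runs$end[k])] <- TRUE
  }
  out
}

#' Label 8-connected components of a binary mask
#'
#' @param mask Logical matrix, `TRUE` = foreground.
#' @return A list with `n` (component count), `sizes` (pixel counts, one per
#'   component), and `labels` (integer matrix, 0 = background).
#' @keywords internal
label_components <- function(mask) {
  runs <- mask_runs(mask)
  nr <- nrow(runs)
  if (nr == 0L) {
    return(list(n = 0L, sizes = integer(0),
                labels = matrix(0L, nrow(mask), ncol(mask))))
  }
  comp <- run_labels(runs)
  lens <- runs$end - runs$start + 1L
  sizes <- as.integer(tapply(lens, comp, sum))
  labels <- matrix(0L, nrow(mask), ncol(mask))
  for (k in seq_len(nr)) {
    labels[cbind(runs$row[k], runs$start[k]:runs$end[k])] <- comp[k]
  }
  list(n = max(comp), sizes = sizes, labels = labels)
}

# Keep only the largest 8-connected component (ties: first label).
largest_component <- function(mask) {
  runs <- mask_runs(mask)
  if (nrow(runs) == 0L) return(mask)
  comp <- run_labels(runs)
  if (max(comp) == 1L) return(mask)
  lens <- runs$end - runs$start + 1L
  sizes <- as.integer(tapply(lens, comp, sum))
  runs_to_mask(runs, which(comp == which.max(sizes)), nrow(mask), ncol(mask))
}

count_components <- function(mask) {
  runs <- mask_runs(mask)
  if (nrow(runs) == 0L) return(0L)
  max(run_labels(runs))
}

# TRUE when some row carries more than one run (a hole requires that).
has_multirun_rows <- function(mask) {
  runs <- mask_runs(mask)
  anyDuplicated(runs$row) > 0L
}
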