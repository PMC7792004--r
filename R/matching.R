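#' Scan-line stereo matching of descriptor sets by SSD
#'
#' Matches two rectified views' descriptor sets under the epipolar
#' constraint: candidate pairs must lie within `band` rows of each other
#' (rectified rows are epipolar scan lines) and have horizontal disparity
#' inside `disparity_range`. For every feature the minimal-SSD candidate
#' is selected; a mutual-best (symmetric) check enforces one-to-one
#' matching, and a match is accepted only if `best <= ssd_max` and
#' `best <= ratio * second_best`. Descriptors are unit vectors, so
#' SSD = 2 (1 - cosine similarity) and lives in 0..4. The mutual-best
#' and ratio filters can be disabled (`ratio = Inf`, `mutual = FALSE`) to
#' reproduce the bare minimal-SSD scan-line rule.
#'
#' Ties in SSD are broken by smaller row difference, then smaller index.
#' Zero-vector (unmatchable) descriptors never enter candidacy.
#'
#' @param set_i,set_j `descriptor_set` objects from
#'   [extract_descriptors()].
#' @param band Scan-line tolerance in rows (>= 0). Default 2.
#' @param disparity_range `c(min, max)` allowed `x_i - x_j` disparity in
#'   pixels. Default unrestricted.
#' @param ssd_max Maximum accepted SSD. Default 1.
#' @param ratio Best/second-best ratio threshold. Default 0.8.
#' @param mutual Require mutual best matches. Default TRUE.
#' @return An object of class `match_set`: data frame with columns
#'   `index_i`, `index_j`, `row_i`, `row_j`, `ssd`, plus attribute `pair`.
#' @export
match_scanline_ssd <- function(set_i, set_j, band = 2,
                               disparity_range = c(-Inf, Inf),
                               ssd_max = 1, ratio = 0.8, mutual = TRUE) {
  stopifnot(inherits(set_i, "descriptor_set"), inherits(set_j, "descriptor_set"))
  if (band < 0) stop("band must be >= 0", call. = FALSE)
  ni <- nrow(set_i$vectors); nj <- nrow(set_j$vectors)
  pair <- c(set_i$camera_id, set_j$camera_id)
  if (ni == 0 || nj == 0) return(empty_match_set(pair))

  # SSD between all pairs; for unit vectors ssd = 2 - 2 cos
  G <- set_i$vectors %*% t(set_j$vectors)
  n2i <- rowSums(set_i$vectors^2); n2j <- rowSums(set_j$vectors^2)
  ssd <- outer(n2i, n2j, "+") - 2 * G
  ssd[ssd < 0] <- 0

  dy <- abs(outer(set_i$y_row, set_j$y_row, "-"))
  disp <- outer(set_i$x, set_j$x, "-")
  ok <- dy <= band & disp >= disparity_range[1] & disp <= disparity_range[2]
  ok[set_i$unmatchable, ] <- FALSE
  ok[, set_j$unmatchable] <- FALSE
  ssd[!ok] <- Inf

  best_j <- best_candidate(ssd, dy)          # per row (feature in i)
  best_i <- best_candidate(t(ssd), t(dy))    # per column

  res <- list()
  for (i in seq_len(ni)) {
    j <- best_j[i]
    if (is.na(j)) next
    if (mutual && (is.na(best_i[j]) || best_i[j] != i)) next
    b <- ssd[i, j]
    if (!(b <= ssd_max)) next
    second <- second_best(ssd[i, ], j)
    if (is.finite(second) && !(b <= ratio * second)) next  # lone candidates pass
    res[[length(res) + 1]] <- data.frame(index_i = i, index_j = j,
                                         row_i = set_i$y_row[i],
                                         row_j = set_j$y_row[j],
                                         ssd = b)
  }
  out <- if (length(res)) do.call(rbind, res) else empty_match_set(pair)
  if (!mutual && nrow(out) > 1) {
    # keep one-to-one even under the bare rule: per j keep the lowest SSD
    # (ties: smaller row difference, then smaller index_i)
    drow <- abs(out$row_i - out$row_j)
    ord <- order(out$index_j, out$ssd, drow, out$index_i)
    out <- out[ord, , drop = FALSE]
    out <- out[!duplicated(out$index_j), , drop = FALSE]
    out <- out[order(out$index_i), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "pair") <- pair
  attr(out, "set_i") <- set_i
  attr(out, "set_j") <- set_j
  class(out) <- c("match_set", "data.frame")
  out
}

# Minimal-SSD candidate per row with deterministic tie-breaking:
# smaller |row difference|, then smaller index.
best_candidate <- function(ssd, dy) {
  apply_rows <- nrow(ssd)
  out <- rep(NA_integer_, apply_rows)
  for (i in seq_len(apply_rows)) {
    v <- ssd[i, ]
    if (all(!is.finite(v))) next
    b <- min(v)
    cand <- which(v == b)
    if (length(cand) > 1) {
      d <- dy[i, cand]
      cand <- cand[d == min(d)]
    }
    out[i] <- cand[1]
  }
  out
}

second_best <- function(v, exclude) {
  v <- v[-exclude]
  v <- v[is.finite(v)]
  if (length(v) == 0) Inf else min(v)
}

empty_match_set <- function(pair) {
  out <- data.frame(index_i = integer(0), index_j = integer(0),
                    row_i = numeric(0), row_j = numeric(0), ssd = numeric(0))
  attr(out, "pair") <- pair
  class(out) <- c("match_set", "data.frame")
  out
}

#' @export
print.match_set <- function(x, ...) {
  pair <- attr(x, "pair")
  cat(sprintf("<match_set> %d match(es)%s\n", nrow(x),
              if (!is.null(pair) && !any(is.na(pair)))
                sprintf(", pair %d|%d", pair[1], pair[2]) else ""))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  invisible(x)
}
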