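# Independent brute-force oracles. These deliberately re-derive results
# from first principles (exhaustive sweeps, explicit loops, generic
# optimizers) rather than sharing code with the package internals.

# ---- connected labelling by iterative min-label propagation ------------
oracle_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(Inf, h, w)
  lab[mask] <- which(mask)
  repeat {
    up <- rbind(Inf, lab[-h, , drop = FALSE])
    dn <- rbind(lab[-1, , drop = FALSE], Inf)
    lf <- cbind(Inf, lab[, -w, drop = FALSE])
    rt <- cbind(lab[, -1, drop = FALSE], Inf)
    new <- pmin(lab, up, dn, lf, rt)
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  labs <- lab[mask]
  split(which(mask), labs)
}

# ---- exhaustive 256-threshold MSER oracle ------------------------------
# Dark-polarity level sets on the supplied intensities; returns one record
# per stable region: level, area, centroid, canonical pixel key.
pixel_key <- function(idx1based, h) {
  i0 <- sort(idx1based) - 1L
  paste(i0 %/% h, i0 %% h, sep = ":", collapse = ";")
}

oracle_mser_polarity <- function(img, delta, min_area, max_area, max_variation) {
  h <- nrow(img); w <- ncol(img)
  nodes <- list()
  node_at_level <- vector("list", 256)  # per level: pixel -> node id
  active <- list()
  for (t in 0:255) {
    comps <- oracle_label(img <= t)
    cur <- list()
    assign_map <- integer(h * w)
    for (C in comps) {
      key <- paste(C, collapse = ",")
      if (!is.null(active[[key]])) {
        id <- active[[key]]
        nodes[[id]]$l1 <- t
      } else {
        id <- length(nodes) + 1L
        i0 <- C - 1L
        nodes[[id]] <- list(pixels = C, area = length(C), l0 = t, l1 = t,
                            seed = min(C),
                            cx = mean(i0 %/% h), cy = mean(i0 %% h),
                            parent = NA_integer_)
      }
      cur[[key]] <- id
      assign_map[C] <- id
    }
    node_at_level[[t + 1]] <- assign_map
    active <- cur
  }
  for (id in seq_along(nodes)) {
    l1 <- nodes[[id]]$l1
    if (l1 < 255) nodes[[id]]$parent <- node_at_level[[l1 + 2]][nodes[[id]]$seed]
  }
  canon <- rep(NA_integer_, length(nodes))
  for (id in seq_along(nodes)) {
    pa <- nodes[[id]]$parent
    if (is.na(pa)) next
    c0 <- canon[pa]
    if (is.na(c0) || nodes[[id]]$area > nodes[[c0]]$area ||
        (nodes[[id]]$area == nodes[[c0]]$area && nodes[[id]]$seed < nodes[[c0]]$seed))
      canon[pa] <- id
  }
  q_at <- function(nid, t) {
    if (t + delta > 255) return(NA_real_)
    m <- nid
    while (t > nodes[[m]]$l1) m <- nodes[[m]]$parent
    while (t < nodes[[m]]$l0) {
      ch <- canon[m]
      if (is.na(ch)) return(NA_real_)
      m <- ch
    }
    up <- m
    while (t + delta > nodes[[up]]$l1) up <- nodes[[up]]$parent
    dn <- m
    while (t - delta < nodes[[dn]]$l0 && !is.na(canon[dn])) dn <- canon[dn]
    (nodes[[up]]$area - nodes[[dn]]$area) / nodes[[m]]$area
  }
  out <- list()
  for (nid in seq_along(nodes)) {
    nd <- nodes[[nid]]
    if (nd$area < min_area || nd$area > max_area) next
    best_q <- NA_real_; best_t <- NA_integer_
    for (t in nd$l0:min(nd$l1, 255 - delta)) {
      q <- q_at(nid, t)
      if (is.na(q) || q > max_variation) next
      qm <- q_at(nid, t - 1); qp <- q_at(nid, t + 1)
      if (!is.na(qm) && !(q <= qm)) next
      if (!is.na(qp) && !(q < qp)) next
      if (is.na(best_t) || q < best_q) { best_q <- q; best_t <- t }
    }
    if (!is.na(best_t))
      out[[length(out) + 1]] <- list(level = best_t, area = nd$area,
                                     cx = nd$cx, cy = nd$cy,
                                     key = pixel_key(nd$pixels, h))
  }
  out
}

oracle_mser <- function(img, delta = 2, min_area = 10, max_area = NULL,
                        max_variation = 0.25) {
  iv <- pmin(pmax(round(img), 0), 255)
  if (is.null(max_area)) max_area <- 0.01 * length(img)
  dark <- oracle_mser_polarity(iv, delta, min_area, max_area, max_variation)
  bright <- oracle_mser_polarity(255 - iv, delta, min_area, max_area, max_variation)
  c(lapply(dark, function(r) { r$polarity <- "dark"; r }),
    lapply(bright, function(r) { r$polarity <- "bright"; r$level <- 255 - r$level; r }))
}

# Canonical multiset signature of a region list for set comparison.
mser_signature <- function(recs) {
  sort(vapply(recs, function(r) paste(r$polarity, r$level, r$key, sep = "|"),
              character(1)))
}

# Signature of detect_mser() output run with region_pixels = TRUE.
detect_signature <- function(ens) {
  regions <- attr(ens, "regions")
  if (nrow(ens) == 0) return(character(0))
  sort(vapply(seq_len(nrow(ens)), function(i) {
    px <- regions[[i]]
    key <- paste(px[order(px[, 1], px[, 2]), 1],
                 px[order(px[, 1], px[, 2]), 2], sep = ":", collapse = ";")
    paste(ens$polarity[i], ens$level[i], key, sep = "|")
  }, character(1)))
}

# ---- brute-force CLAHE reference (explicit loops) ----------------------
oracle_clahe <- function(img, tiles, clip_limit, n_bins) {
  h <- nrow(img); w <- ncol(img)
  tr <- tiles[1]; tc <- tiles[2]
  v <- pmin(pmax(round(img), 0), 255)
  maps <- array(0, c(tr, tc, n_bins))
  cr <- numeric(tr); ccent <- numeric(tc)
  for (ti in 1:tr) {
    rows <- which(floor((0:(h - 1)) * tr / h) + 1 == ti)
    cr[ti] <- (min(rows) - 1 + max(rows) - 1) / 2
    for (tj in 1:tc) {
      cols <- which(floor((0:(w - 1)) * tc / w) + 1 == tj)
      ccent[tj] <- (min(cols) - 1 + max(cols) - 1) / 2
      hist <- rep(0, n_bins)
      for (r in rows) for (cc in cols) {
        b <- floor(v[r, cc] * n_bins / 256) + 1
        hist[b] <- hist[b] + 1
      }
      cl <- clip_limit * length(rows) * length(cols)
      excess <- sum(pmax(hist - cl, 0))
      hist <- pmin(hist, cl) + excess / n_bins
      cdf <- cumsum(hist) / sum(hist)
      maps[ti, tj, ] <- round(cdf * 255)
    }
  }
  bracket <- function(pos, centers) {
    n <- length(centers)
    if (n == 1 || pos <= centers[1]) return(c(1, min(2, n), 0))
    if (pos >= centers[n]) return(c(max(n - 1, 1), n, 1))
    i <- max(which(centers <= pos))
    i <- min(i, n - 1)
    f <- (pos - centers[i]) / (centers[i + 1] - centers[i])
    c(i, i + 1, f)
  }
  out <- matrix(0, h, w)
  for (r in 1:h) for (cc in 1:w) {
    b <- floor(v[r, cc] * n_bins / 256) + 1
    by <- bracket(r - 1, cr); bx <- bracket(cc - 1, ccent)
    val <- (1 - by[3]) * (1 - bx[3]) * maps[by[1], bx[1], b] +
           (1 - by[3]) * bx[3] * maps[by[1], bx[2], b] +
           by[3] * (1 - bx[3]) * maps[by[2], bx[1], b] +
           by[3] * bx[3] * maps[by[2], bx[2], b]
    out[r, cc] <- round(val)
  }
  out
}

# ---- exhaustive all-pairs scan-line matching oracle --------------------
oracle_match <- function(set_i, set_j, band = 2, disparity_range = c(-Inf, Inf),
                         ssd_max = 1, ratio = 0.8, mutual = TRUE) {
  ni <- nrow(set_i$vectors); nj <- nrow(set_j$vectors)
  ssd <- matrix(Inf, ni, nj)
  for (i in seq_len(ni)) for (j in seq_len(nj)) {
    if (set_i$unmatchable[i] || set_j$unmatchable[j]) next
    if (abs(set_i$y_row[i] - set_j$y_row[j]) > band) next
    disp <- set_i$x[i] - set_j$x[j]
    if (disp < disparity_range[1] || disp > disparity_range[2]) next
    ssd[i, j] <- sum((set_i$vectors[i, ] - set_j$vectors[j, ])^2)
  }
  pick <- function(v, dy) {
    fin <- which(is.finite(v))
    if (!length(fin)) return(NA_integer_)
    b <- min(v[fin])
    cand <- fin[v[fin] == b]
    if (length(cand) > 1) cand <- cand[dy[cand] == min(dy[cand])]
    cand[1]
  }
  res <- NULL
  for (i in seq_len(ni)) {
    dy_i <- abs(set_i$y_row[i] - set_j$y_row)
    j <- pick(ssd[i, ], dy_i)
    if (is.na(j)) next
    if (mutual) {
      dy_j <- abs(set_j$y_row[j] - set_i$y_row)
      ib <- pick(ssd[, j], dy_j)
      if (is.na(ib) || ib != i) next
    }
    b <- ssd[i, j]
    if (!(b <= ssd_max)) next
    others <- ssd[i, -j]
    second <- if (any(is.finite(others))) min(others[is.finite(others)]) else Inf
    if (is.finite(second) && !(b <= ratio * second)) next
    res <- rbind(res, data.frame(index_i = i, index_j = j, ssd = b))
  }
  if (is.null(res)) data.frame(index_i = integer(0), index_j = integer(0),
                               ssd = numeric(0)) else res
}

# ---- numerical two-parameter ray-distance minimization -----------------
oracle_triangulate <- function(o1, d1, o2, d2) {
  d1 <- d1 / sqrt(sum(d1^2)); d2 <- d2 / sqrt(sum(d2^2))
  f <- function(p) sum((o1 + p[1] * d1 - o2 - p[2] * d2)^2)
  g <- as.matrix(expand.grid(s = seq(-300, 300, by = 10),
                             t = seq(-300, 300, by = 10)))
  v <- apply(g, 1, f)
  p0 <- g[which.min(v), ]
  opt <- stats::optim(p0, f, method = "BFGS",
                      control = list(reltol = 1e-16, maxit = 500))
  # polish with finite-difference Newton steps (f is quadratic)
  par <- opt$par
  eps <- 1e-4
  for (it in 1:6) {
    g <- c((f(par + c(eps, 0)) - f(par - c(eps, 0))) / (2 * eps),
           (f(par + c(0, eps)) - f(par - c(0, eps))) / (2 * eps))
    H <- matrix(0, 2, 2)
    H[1, 1] <- (f(par + c(eps, 0)) - 2 * f(par) + f(par - c(eps, 0))) / eps^2
    H[2, 2] <- (f(par + c(0, eps)) - 2 * f(par) + f(par - c(0, eps))) / eps^2
    H[1, 2] <- H[2, 1] <- (f(par + c(eps, eps)) - f(par + c(eps, -eps)) -
                           f(par + c(-eps, eps)) + f(par + c(-eps, -eps))) / (4 * eps^2)
    step <- tryCatch(solve(H, g), error = function(e) c(0, 0))
    par <- par - step
    if (max(abs(step)) < 1e-12) break
  }
  p1 <- o1 + par[1] * d1
  p2 <- o2 + par[2] * d2
  list(point = (p1 + p2) / 2, e = sqrt(max(f(par), 0)))
}

# ---- exhaustive-triple MSAC oracle -------------------------------------
oracle_msac <- function(P, threshold) {
  n <- nrow(P)
  t2 <- threshold^2
  best <- NULL
  for (tri in utils::combn(n, 3, simplify = FALSE)) {
    v1 <- P[tri[2], ] - P[tri[1], ]; v2 <- P[tri[3], ] - P[tri[1], ]
    nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
             v1[3] * v2[1] - v1[1] * v2[3],
             v1[1] * v2[2] - v1[2] * v2[1])
    nn <- sqrt(sum(nrm^2))
    if (nn < 1e-12) next
    nrm <- nrm / nn
    off <- sum(nrm * P[tri[1], ])
    cost <- sum(pmin((P %*% nrm - off)^2, t2))
    if (is.null(best) || cost < best$cost)
      best <- list(cost = cost, normal = nrm, offset = off)
  }
  res <- as.numeric(P %*% best$normal - best$offset)
  inl <- abs(res) <= threshold
  if (sum(inl) >= 3) {
    Q <- P[inl, , drop = FALSE]
    ctr <- colMeans(Q)
    ev <- eigen(crossprod(sweep(Q, 2, ctr)), symmetric = TRUE)
    nrm <- ev$vectors[, 3] / sqrt(sum(ev$vectors[, 3]^2))
    if (sum(nrm * best$normal) < 0) nrm <- -nrm
    off <- sum(nrm * ctr)
    best$normal <- nrm; best$offset <- off
  }
  res <- as.numeric(P %*% best$normal - best$offset)
  list(normal = best$normal, offset = best$offset,
       inliers = abs(res) <= threshold)
}

# ---- exhaustive optimal assignment (n <= 6) ----------------------------
oracle_assignment <- function(D, G, cap) {
  nd <- nrow(D); ng <- nrow(G)
  n <- min(nd, ng)
  dist <- sqrt(outer(rowSums(D^2), rowSums(G^2), "+") - 2 * D %*% t(G))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- NULL
  for (p in perms(seq_len(ng))) {
    sel <- p[seq_len(n)]
    d <- dist[cbind(seq_len(n), sel)]
    ok <- d <= cap
    tot <- sum(d[ok]) - 1e6 * sum(ok)  # maximize matches, then min distance
    if (is.null(best) || tot < best$tot)
      best <- list(tot = tot, det = seq_len(n)[ok], gt = sel[ok])
  }
  best
}

# ---- longhand descriptive statistics -----------------------------------
oracle_stats <- function(e) {
  n <- length(e)
  m <- sum(e) / n
  s <- if (n > 1) sqrt(sum((e - m)^2) / (n - 1)) else 0
  srt <- sort(e)
  q7 <- function(p) {
    hh <- (n - 1) * p
    lo <- floor(hh)
    if (lo + 2 > n) return(srt[n])
    srt[lo + 1] + (hh - lo) * (srt[lo + 2] - srt[lo + 1])
  }
  list(mean = m, sd = s, rms = sqrt(sum(e^2) / n), min = srt[1],
       q1 = q7(0.25), median = q7(0.5), q3 = q7(0.75), max = srt[n])
}

# ---- dense-grid fast-Hessian determinant at one location ---------------
# Literal nested-loop box sums; returns the det response for lobe size l
# at 0-based center (x, y).
oracle_hessian_det <- function(img, x, y, l) {
  box <- function(r1, c1, r2, c2) {
    s <- 0
    for (r in r1:r2) for (cc in c1:c2) s <- s + img[r + 1, cc + 1]
    s
  }
  L <- 3 * l; hw <- (l - 1) / 2
  dyy <- box(y - hw - l, x - (l - 1), y - hw - 1, x + (l - 1)) +
         box(y + hw + 1, x - (l - 1), y + hw + l, x + (l - 1)) -
         2 * box(y - hw, x - (l - 1), y + hw, x + (l - 1))
  dxx <- box(y - (l - 1), x - hw - l, y + (l - 1), x - hw - 1) +
         box(y - (l - 1), x + hw + 1, y + (l - 1), x + hw + l) -
         2 * box(y - hw, x - hw, y + hw, x + hw)
  dxy <- box(y - l, x - l, y - 1, x - 1) + box(y + 1, x + 1, y + l, x + l) -
         box(y - l, x + 1, y - 1, x + l) - box(y + 1, x - l, y + l, x - 1)
  (dxx / L^2) * (dyy / L^2) - (0.9 * dxy / L^2)^2
}
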