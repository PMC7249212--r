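# Planar polygon primitives for fire-front maintenance.
#
# Rings are n x 2 matrices of vertices, stored OPEN (the first vertex is not
# repeated at the end) and oriented counter-clockwise, so the burned area is
# to the left of each directed edge and the outward normal is the right-hand
# normal. All coordinates are projected metres.

ring_close <- function(ring) rbind(ring, ring[1, , drop = FALSE])

# Signed shoelace area; positive for CCW rings.
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

ensure_ccw <- function(ring) {
  if (ring_area(ring) < 0) ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  else ring
}

# Outward vertex normals of a CCW ring: the normalized bisector of the two
# adjacent edge normals; falls back to the following edge's normal when the
# bisector degenerates (collinear back-and-forth vertices).
ring_normals <- function(ring) {
  n <- nrow(ring)
  nxt <- c(2:n, 1)
  ex <- ring[nxt, 1] - ring[, 1]
  ey <- ring[nxt, 2] - ring[, 2]
  len <- sqrt(ex^2 + ey^2)
  len[len == 0] <- 1
  # right-hand normal of each edge (outward for CCW)
  enx <- ey / len; eny <- -ex / len
  prv <- c(n, 1:(n - 1))
  vx <- enx[prv] + enx; vy <- eny[prv] + eny
  vlen <- sqrt(vx^2 + vy^2)
  deg <- vlen < 1e-12
  vx[deg] <- enx[deg]; vy[deg] <- eny[deg]
  vlen[deg] <- 1
  cbind(vx / vlen, vy / vlen)
}

# Winding number of each point with respect to one ring (vectorized over
# points). Nonzero winding = inside.
ring_winding <- function(ring, px, py) {
  n <- nrow(ring)
  wn <- integer(length(px))
  x1 <- ring[, 1]; y1 <- ring[, 2]
  nxt <- c(2:n, 1)
  x2 <- ring[nxt, 1]; y2 <- ring[nxt, 2]
  for (i in seq_len(n)) {
    isl <- (x2[i] - x1[i]) * (py - y1[i]) - (px - x1[i]) * (y2[i] - y1[i])
    up <- y1[i] <= py & y2[i] > py & isl > 0
    dn <- y1[i] > py & y2[i] <= py & isl < 0
    wn <- wn + up - dn
  }
  wn
}

# TRUE for points strictly inside the union (nonzero total winding) of a
# list of rings.
points_in_rings <- function(rings, px, py) {
  wn <- integer(length(px))
  for (ring in rings) wn <- wn + ring_winding(ring, px, py)
  wn != 0
}

# Minimum Euclidean distance from points to the boundary of a ring set;
# 0 for points inside the union.
points_ring_distance <- function(rings, px, py) {
  d2 <- rep(Inf, length(px))
  for (ring in rings) {
    n <- nrow(ring)
    nxt <- c(2:n, 1)
    ax <- ring[, 1]; ay <- ring[, 2]
    bx <- ring[nxt, 1]; by <- ring[nxt, 2]
    dx <- bx - ax; dy <- by - ay
    ll <- dx^2 + dy^2
    ll[ll == 0] <- 1
    for (i in seq_len(n)) {
      t <- pmin(pmax(((px - ax[i]) * dx[i] + (py - ay[i]) * dy[i]) / ll[i],
                     0), 1)
      qx <- ax[i] + t * dx[i] - px
      qy <- ay[i] + t * dy[i] - py
      d2 <- pmin(d2, qx^2 + qy^2)
    }
  }
  d <- sqrt(d2)
  d[points_in_rings(rings, px, py)] <- 0
  d
}

# --- segment intersection machinery -----------------------------------------

# All segments of a ring list as one table with provenance.
rings_segments <- function(rings) {
  segs <- lapply(seq_along(rings), function(k) {
    ring <- rings[[k]]
    n <- nrow(ring)
    nxt <- c(2:n, 1)
    cbind(ring = k, edge = seq_len(n),
          ax = ring[, 1], ay = ring[, 2],
          bx = ring[nxt, 1], by = ring[nxt, 2])
  })
  do.call(rbind, segs)
}

# Proper pairwise intersections among segments (excluding pairs of adjacent
# edges of the same ring, which share an endpoint by construction).
# Returns a data.frame with segment indices i, j and the intersection point.
segment_intersections <- function(seg) {
  m <- nrow(seg)
  if (m < 2) return(NULL)
  # bounding-box prefilter over all pairs
  xmin <- pmin(seg[, "ax"], seg[, "bx"]); xmax <- pmax(seg[, "ax"], seg[, "bx"])
  ymin <- pmin(seg[, "ay"], seg[, "by"]); ymax <- pmax(seg[, "ay"], seg[, "by"])
  idx <- which(upper.tri(matrix(TRUE, m, m)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  keep <- xmin[i] <= xmax[j] & xmin[j] <= xmax[i] &
    ymin[i] <= ymax[j] & ymin[j] <= ymax[i]
  i <- i[keep]; j <- j[keep]
  if (!length(i)) return(NULL)
  # drop adjacent edges of the same ring
  same <- seg[i, "ring"] == seg[j, "ring"]
  nseg <- tapply(seg[, "edge"], seg[, "ring"], max)
  nr <- nseg[as.character(seg[i, "ring"])]
  de <- abs(seg[i, "edge"] - seg[j, "edge"])
  adj <- same & (de == 1 | de == nr - 1)
  i <- i[!adj]; j <- j[!adj]
  if (!length(i)) return(NULL)
  # parametric intersection
  r_x <- seg[i, "bx"] - seg[i, "ax"]; r_y <- seg[i, "by"] - seg[i, "ay"]
  s_x <- seg[j, "bx"] - seg[j, "ax"]; s_y <- seg[j, "by"] - seg[j, "ay"]
  den <- r_x * s_y - r_y * s_x
  qpx <- seg[j, "ax"] - seg[i, "ax"]; qpy <- seg[j, "ay"] - seg[i, "ay"]
  ok <- abs(den) > 1e-12
  t <- ifelse(ok, (qpx * s_y - qpy * s_x) / den, NA_real_)
  u <- ifelse(ok, (qpx * r_y - qpy * r_x) / den, NA_real_)
  eps <- 1e-9
  hit <- ok & t > eps & t < 1 - eps & u > eps & u < 1 - eps
  if (!any(hit)) return(NULL)
  data.frame(i = i[hit], j = j[hit],
             ti = t[hit], tj = u[hit],
             x = seg[i[hit], "ax"] + t[hit] * r_x[hit],
             y = seg[i[hit], "ay"] + t[hit] * r_y[hit])
}

# --- union / repair ----------------------------------------------------------

# Union of a set of (possibly self-intersecting, possibly overlapping) CCW
# rings under the nonzero winding rule, returning the exterior boundary
# ring(s). Interior holes are discarded: once burned, an enclosed pocket is
# treated as burned too, which keeps the burned area monotone.
union_rings <- function(rings, min_area = 1e-9) {
  rings <- Filter(function(r) nrow(r) >= 3 && abs(ring_area(r)) > min_area,
                  rings)
  rings <- lapply(rings, ensure_ccw)
  if (length(rings) == 0) return(rings)
  seg <- rings_segments(rings)
  xs <- segment_intersections(seg)
  if (is.null(xs)) {
    if (length(rings) == 1) return(rings)
    # no crossings: drop rings wholly contained in another. Containment
    # requires EVERY vertex inside — a single vertex can sit exactly on
    # another ring's boundary at the moment two fronts first touch, and a
    # point-on-boundary winding test is unreliable.
    keep <- rep(TRUE, length(rings))
    for (k in seq_along(rings)) {
      others <- rings[-k][keep[-k]]
      if (length(others) &&
          all(points_in_rings(others, rings[[k]][, 1], rings[[k]][, 2])))
        keep[k] <- FALSE
    }
    return(rings[keep])
  }
  # split each segment at its intersection parameters
  pieces_a <- vector("list", nrow(seg))
  for (s in seq_len(nrow(seg))) {
    ts <- sort(c(xs$ti[xs$i == s], xs$tj[xs$j == s]))
    ts <- c(0, ts, 1)
    ax <- seg[s, "ax"]; ay <- seg[s, "ay"]
    dx <- seg[s, "bx"] - ax; dy <- seg[s, "by"] - ay
    px <- ax + ts * dx; py <- ay + ts * dy
    k <- length(ts) - 1
    pieces_a[[s]] <- cbind(ax = px[1:k], ay = py[1:k],
                           bx = px[2:(k + 1)], by = py[2:(k + 1)])
  }
  pc <- do.call(rbind, pieces_a)
  lens <- sqrt((pc[, "bx"] - pc[, "ax"])^2 + (pc[, "by"] - pc[, "ay"])^2)
  pc <- pc[lens > 1e-9, , drop = FALSE]
  lens <- lens[lens > 1e-9]
  # keep pieces on the union boundary: inside on the left, outside on the
  # right (nonzero rule over all rings)
  mx <- (pc[, "ax"] + pc[, "bx"]) / 2
  my <- (pc[, "ay"] + pc[, "by"]) / 2
  nx <- (pc[, "by"] - pc[, "ay"]) / lens   # right-hand normal
  ny <- -(pc[, "bx"] - pc[, "ax"]) / lens
  scale <- max(abs(range(pc))) + 1
  eps <- 1e-7 * scale
  out_in <- points_in_rings(rings, mx + eps * nx, my + eps * ny)
  in_in <- points_in_rings(rings, mx - eps * nx, my - eps * ny)
  keep <- in_in & !out_in
  pc <- pc[keep, , drop = FALSE]
  if (nrow(pc) < 3) return(rings)   # degenerate; keep input unrepaired
  stitch_pieces(pc)
}

# Stitch directed boundary pieces (interior on the left) into closed CCW
# rings by endpoint matching; ambiguous junctions take the sharpest left
# turn. CW output rings are holes and are dropped.
stitch_pieces <- function(pc, tol = 1e-6) {
  key <- function(x, y) paste(round(x / tol), round(y / tol))
  starts <- key(pc[, "ax"], pc[, "ay"])
  start_map <- split(seq_len(nrow(pc)), starts)
  used <- rep(FALSE, nrow(pc))
  rings <- list()
  for (s0 in seq_len(nrow(pc))) {
    if (used[s0]) next
    path <- s0
    used[s0] <- TRUE
    repeat {
      cur <- path[length(path)]
      k <- key(pc[cur, "bx"], pc[cur, "by"])
      cand <- start_map[[k]]
      cand <- cand[!used[cand]]
      closes <- identical(k, key(pc[s0, "ax"], pc[s0, "ay"])) &&
        length(path) >= 3
      # closing the ring competes with the other continuations at a junction
      if (closes) cand <- c(cand, s0)
      if (!length(cand)) break
      if (length(cand) > 1) {
        # sharpest left turn relative to the incoming direction
        din <- c(pc[cur, "bx"] - pc[cur, "ax"], pc[cur, "by"] - pc[cur, "ay"])
        ang <- vapply(cand, function(cc) {
          dout <- c(pc[cc, "bx"] - pc[cc, "ax"], pc[cc, "by"] - pc[cc, "ay"])
          atan2(din[1] * dout[2] - din[2] * dout[1],
                din[1] * dout[1] + din[2] * dout[2])
        }, numeric(1))
        cand <- cand[which.max(ang)]
      } else cand <- cand[1]
      if (closes && cand == s0) {
        ring <- cbind(pc[path, "ax"], pc[path, "ay"])
        if (ring_area(ring) > 0) rings[[length(rings) + 1]] <- ring
        break
      }
      path <- c(path, cand)
      used[cand] <- TRUE
    }
  }
  if (!length(rings)) return(list())
  rings
}

# Refine a ring for the next displacement step: split edges longer than
# 1.5x the target spacing by linear interpolation and merge vertices closer
# than spacing/20. Existing vertices are preserved so that pure radial
# growth stays exact.
resample_ring <- function(ring, spacing) {
  n <- nrow(ring)
  nxt <- c(2:n, 1)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- ring[i, ]; b <- ring[nxt[i], ]
    len <- sqrt(sum((b - a)^2))
    if (len > 1.5 * spacing) {
      k <- ceiling(len / spacing)
      t <- (0:(k - 1)) / k
      out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
    } else {
      out[[i]] <- matrix(a, 1, 2)
    }
  }
  r <- do.call(rbind, out)
  # merge near-duplicates
  n <- nrow(r)
  prv <- c(n, 1:(n - 1))
  d <- sqrt((r[, 1] - r[prv, 1])^2 + (r[, 2] - r[prv, 2])^2)
  r <- r[d > spacing / 20, , drop = FALSE]
  if (nrow(r) < 3) ring else r
}

# Regular k-gon ring of given radius around a centre, CCW.
regular_ring <- function(center, radius, k = 16) {
  a <- 2 * pi * (0:(k - 1)) / k
  cbind(center[1] + radius * cos(a), center[2] + radius * sin(a))
}
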