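# Independent oracles used by the tests. Everything here is written in plain
# R against the definitions, deliberately independent of the engine's C++
# implementation.

DELTA <- 500 / 24

hex_xy <- function(q, r) cbind(x = q + r / 2, y = sqrt(3) / 2 * r)

# exhaustive Euclidean scan over every bone site (micrometres)
dmin_exhaustive <- function(label, q, r) {
  bone <- which(label == 0L, arr.ind = TRUE)
  stopifnot(nrow(bone) > 0)
  bq <- bone[, 2] - 1L
  br <- bone[, 1] - 1L
  p0 <- hex_xy(q, r)
  pb <- hex_xy(bq, br)
  DELTA * sqrt(min((pb[, 1] - p0[1])^2 + (pb[, 2] - p0[2])^2))
}

# plain breadth-first-search distance (lattice steps) to the nearest site
# satisfying pred(label_value); -Inf if unreachable
bfs_distance <- function(label, q, r, pred) {
  n <- nrow(label)
  seen <- matrix(FALSE, n, n)
  frontier <- cbind(q = q, r = r)
  seen[r + 1, q + 1] <- TRUE
  d <- 0
  offs <- cbind(q = c(1L, -1L, 0L, 0L, 1L, -1L), r = c(0L, 0L, 1L, -1L, -1L, 1L))
  while (nrow(frontier) > 0) {
    d <- d + 1
    nxt <- NULL
    for (i in seq_len(nrow(frontier))) {
      for (k in 1:6) {
        nq <- frontier[i, 1] + offs[k, 1]
        nr <- frontier[i, 2] + offs[k, 2]
        if (nq < 0 || nr < 0 || nq >= n || nr >= n) next
        if (seen[nr + 1, nq + 1]) next
        seen[nr + 1, nq + 1] <- TRUE
        if (pred(label[nr + 1, nq + 1])) return(d)
        nxt <- rbind(nxt, c(nq, nr))
      }
    }
    frontier <- if (is.null(nxt)) matrix(integer(0), 0, 2) else nxt
  }
  -Inf
}

# depth-first enumeration of all simple paths from (q, r) until a predicate
# site is hit, pruned at the best length found; returns the minimum length
enumerate_min_path <- function(label, q, r, pred, cap = 12L) {
  n <- nrow(label)
  best <- cap + 1L
  offs <- cbind(c(1L, -1L, 0L, 0L, 1L, -1L), c(0L, 0L, 1L, -1L, -1L, 1L))
  visited <- matrix(FALSE, n, n)
  recurse <- function(cq, cr, depth) {
    if (depth >= best) return(invisible(NULL))
    for (k in 1:6) {
      nq <- cq + offs[k, 1]
      nr <- cr + offs[k, 2]
      if (nq < 0 || nr < 0 || nq >= n || nr >= n) next
      if (visited[nr + 1, nq + 1]) next
      if (pred(label[nr + 1, nq + 1])) {
        if (depth + 1L < best) best <<- depth + 1L
        next
      }
      visited[nr + 1, nq + 1] <<- TRUE
      recurse(nq, nr, depth + 1L)
      visited[nr + 1, nq + 1] <<- FALSE
    }
    invisible(NULL)
  }
  visited[r + 1, q + 1] <- TRUE
  recurse(q, r, 0L)
  if (best > cap) -Inf else best
}

# clock-explicit, geometry-free branching simulation of the Control count
# process: cells carry a phase (hours until eligibility = 24 - phase); one
# categorical fate draw per eligibility. Returns final normalized sizes and
# extinction flags for m independent members.
branching_oracle <- function(m, n0, hours = 360, alpha1 = 0.4, alpha2 = 0.1,
                             daughter_mode = c("zero", "random")) {
  daughter_mode <- match.arg(daughter_mode)
  final <- numeric(m)
  extinct <- logical(m)
  for (j in seq_len(m)) {
    v <- tabulate(sample.int(24, n0, replace = TRUE), nbins = 24)
    for (t in seq_len(hours)) {
      e <- v[24]
      v <- c(0L, v[1:23])
      if (e > 0) {
        f <- as.vector(rmultinom(1, e, c(alpha2, alpha1, 1 - alpha1 - alpha2)))
        v[1] <- v[1] + f[2] + f[3] # surviving mothers restart a full cycle
        if (f[2] > 0) {
          if (daughter_mode == "zero") {
            v[1] <- v[1] + f[2]
          } else {
            v <- v + as.vector(rmultinom(1, f[2], rep(1, 24)))
          }
        }
      }
      if (sum(v) == 0) break
    }
    final[j] <- sum(v) / n0
    extinct[j] <- sum(v) == 0
  }
  list(final = final, extinct = extinct)
}

# ---- state construction and invariant checks --------------------------------

# build a lattice state by hand from a label matrix (clocks given or zero)
make_state <- function(label, clock = NULL) {
  if (is.null(clock)) {
    clock <- matrix(-1L, nrow(label), ncol(label))
    clock[label == 2L] <- 0L
  }
  st <- initialize_lesion(lesion_config(2, 1, n = nrow(label)), seed = 1)
  st$label <- label
  st$clock <- clock
  st
}

count_non_tumour_neighbours <- function(label, q, r) {
  n <- nrow(label)
  offs <- cbind(c(1L, -1L, 0L, 0L, 1L, -1L), c(0L, 0L, 1L, -1L, -1L, 1L))
  cnt <- 0L
  for (k in 1:6) {
    nq <- q + offs[k, 1]
    nr <- r + offs[k, 2]
    if (nq < 0 || nr < 0 || nq >= n || nr >= n || label[nr + 1, nq + 1] != 2L) {
      cnt <- cnt + 1L
    }
  }
  cnt
}

# no tumour site adjacent to a bone site
has_tumour_bone_contact <- function(label) {
  n <- nrow(label)
  tum <- which(label == 2L, arr.ind = TRUE)
  if (nrow(tum) == 0) return(FALSE)
  offs <- cbind(c(1L, -1L, 0L, 0L, 1L, -1L), c(0L, 0L, 1L, -1L, -1L, 1L))
  for (i in seq_len(nrow(tum))) {
    q <- tum[i, 2] - 1L
    r <- tum[i, 1] - 1L
    for (k in 1:6) {
      nq <- q + offs[k, 1]
      nr <- r + offs[k, 2]
      if (nq < 0 || nr < 0 || nq >= n || nr >= n) next
      if (label[nr + 1, nq + 1] == 0L) return(TRUE)
    }
  }
  FALSE
}

expect_state_invariants <- function(state, bone_before = NULL) {
  label <- state$label
  expect_true(all(label %in% c(0L, 1L, 2L)))
  expect_false(has_tumour_bone_contact(label))
  if (!is.null(bone_before)) {
    expect_lte(sum(label == 0L), bone_before)
  }
  clocks <- state$clock[label == 2L]
  expect_true(all(clocks >= 0 & clocks <= 24))
  expect_true(all(state$clock[label != 2L] == -1L))
  invisible(sum(label == 0L))
}

# any non-tumour pocket unreachable from the border through non-tumour sites
has_interior_hole <- function(label) {
  n <- nrow(label)
  open <- label != 2L
  seen <- matrix(FALSE, n, n)
  frontier <- which(open & (row(label) %in% c(1, n) | col(label) %in% c(1, n)))
  seen[frontier] <- TRUE
  offs <- cbind(c(1L, -1L, 0L, 0L, 1L, -1L), c(0L, 0L, 1L, -1L, -1L, 1L))
  while (length(frontier) > 0) {
    nxt <- integer(0)
    r0 <- (frontier - 1L) %% n
    q0 <- (frontier - 1L) %/% n
    for (k in 1:6) {
      nq <- q0 + offs[k, 1]
      nr <- r0 + offs[k, 2]
      ok <- nq >= 0 & nq < n & nr >= 0 & nr < n
      idx <- nr[ok] + 1L + nq[ok] * n
      idx <- idx[open[idx] & !seen[idx]]
      seen[idx] <- TRUE
      nxt <- c(nxt, idx)
    }
    frontier <- unique(nxt)
  }
  any(open & !seen)
}

# hexagonal disc of tumour with a 1-px margin ring, centred on an n x n grid
make_disc_state <- function(radius, n = 7 + 2 * radius, clock_value = 0L) {
  c0 <- n %/% 2
  label <- matrix(0L, n, n)
  for (q in 0:(n - 1)) for (r in 0:(n - 1)) {
    d <- (abs(q - c0) + abs(r - c0) + abs((q - c0) + (r - c0))) / 2
    if (d <= radius) label[r + 1, q + 1] <- 2L
    else if (d <= radius + 1) label[r + 1, q + 1] <- 1L
  }
  clock <- matrix(-1L, n, n)
  clock[label == 2L] <- clock_value
  make_state(label, clock)
}
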