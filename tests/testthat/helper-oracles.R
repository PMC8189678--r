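# Independent reference implementations used as oracles. These must stay
# independent of the package code paths they check: different algebra for
# the torsion angle, a recursive reference for the remapper, an explicit
# Lance-Williams recurrence for Ward linkage, and a replicate-points KDE.

# torsion via projection onto the plane orthogonal to the central bond
# (vector-algebra formulation distinct from the package's normal-vector one)
oracle_dihedral <- function(p1, p2, p3, p4) {
  e <- p3 - p2
  e <- e / sqrt(sum(e^2))
  u <- p1 - p2
  v <- p4 - p3
  w1 <- u - sum(u * e) * e
  w2 <- v - sum(v * e) * e
  det3 <- function(a, b) sum(e * c(a[2] * b[3] - a[3] * b[2],
                                   a[3] * b[1] - a[1] * b[3],
                                   a[1] * b[2] - a[2] * b[1]))
  ang <- atan2(det3(w1, w2), sum(w1 * w2)) * 180 / pi
  ((ang %% 360) + 360) %% 360
}

# random rigid motion: proper rotation (det +1) plus translation
random_rigid_motion <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = rnorm(3, sd = 50))
}

apply_rigid_motion_chain <- function(chain, motion) {
  for (i in seq_along(chain$residues)) {
    at <- chain$residues[[i]]$atoms
    if (is.null(at)) next
    chain$residues[[i]]$atoms <- at %*% t(motion$R) +
      matrix(motion$t, nrow(at), 3, byrow = TRUE)
  }
  chain
}

# ---- remap reference -----------------------------------------------------

# Recursive reference mapper: consumes the two symbol vectors from the
# left, re-deriving the case rules independently at every step. Returns
# list(alignment_column, homology_known) or the string "mismatch".
oracle_remap <- function(s3, sa) {
  c3 <- strsplit(chartr("acgu", "ACGU", s3), "")[[1]]
  ca <- strsplit(chartr("acgu", "ACGU", sa), "")[[1]]
  n3 <- length(c3)
  na_ <- length(ca)
  rec <- function(i, j) {
    if (i > n3) {
      if (j <= na_ && any(!ca[j:na_] %in% c("-", "."))) return("mismatch")
      return(list(alignment_column = integer(0),
                  homology_known = logical(0)))
    }
    h3 <- c3[[i]]
    if (j > na_) {
      if (h3 != "-") return("mismatch")
      rest <- rec(i + 1L, j)
      if (identical(rest, "mismatch")) return("mismatch")
      return(list(alignment_column = c(NA_integer_, rest$alignment_column),
                  homology_known = c(FALSE, rest$homology_known)))
    }
    consume <- function(col_used, known, jnext) {
      rest <- rec(i + 1L, jnext)
      if (identical(rest, "mismatch")) return("mismatch")
      list(alignment_column = c(col_used, rest$alignment_column),
           homology_known = c(known, rest$homology_known))
    }
    ha <- ca[[j]]
    if (h3 == ha) return(consume(j, TRUE, j + 1L))
    if (h3 == "-") {
      win <- j
      while (win <= na_ && ca[[win]] %in% c("-", ".")) win <- win + 1L
      cand <- if (win > j) j:(win - 1L) else integer(0)
      hit <- cand[ca[cand] == "-"][1]
      if (is.na(hit)) hit <- cand[ca[cand] == "."][1]
      if (!is.na(hit)) return(consume(hit, TRUE, hit + 1L))
      return(consume(NA_integer_, FALSE, j))
    }
    if (ha %in% c("-", ".")) return(rec(i, j + 1L))
    "mismatch"
  }
  rec(1L, 1L)
}

# all strings of lengths 1..max_len over an alphabet
enumerate_strings <- function(alphabet, max_len) {
  out <- character(0)
  for (L in seq_len(max_len)) {
    g <- do.call(expand.grid,
                 c(rep(list(alphabet), L), stringsAsFactors = FALSE))
    out <- c(out, do.call(paste0, g))
  }
  out
}

degap <- function(x) gsub("[-.]", "", chartr("acgu", "ACGU", x))

# ---- Ward linkage reference ---------------------------------------------

# Plain Lance-Williams agglomeration for Ward (ward.D2 form, squared
# distances in the recurrence). Returns merge heights and the member sets
# merged at each step.
oracle_ward <- function(d) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1L, n)
  heights <- numeric(0)
  merges <- list()
  for (step in seq_len(n - 1L)) {
    best <- c(NA, NA)
    bestv <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        v <- d2[active[ii], active[jj]]
        if (v < bestv - 1e-12) {
          bestv <- v
          best <- c(ii, jj)
        }
      }
    }
    i <- active[best[1]]; j <- active[best[2]]
    heights <- c(heights, sqrt(bestv))
    merges[[step]] <- sort(c(members[[i]], members[[j]]))
    ni <- sizes[i]; nj <- sizes[j]
    for (k in active) {
      if (k == i || k == j) next
      nk <- sizes[k]
      d2[i, k] <- d2[k, i] <-
        ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
        (ni + nj + nk)
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  list(heights = heights, merges = merges)
}

# member sets merged at each step of an hclust tree
hclust_merge_sets <- function(hc) {
  sets <- list()
  out <- list()
  for (s in seq_len(nrow(hc$merge))) {
    get <- function(v) if (v < 0) -v else sets[[v]]
    sets[[s]] <- sort(c(get(hc$merge[s, 1]), get(hc$merge[s, 2])))
    out[[s]] <- sets[[s]]
  }
  out
}

# ---- KDE reference -------------------------------------------------------

# Naive replicate-points KDE: every point copied at all 25 combinations of
# +/- {0,1,2}*360 shifts on both axes, plain product-Gaussian evaluation.
oracle_kde_grid <- function(points, centres, bandwidth) {
  shifts <- (-2:2) * 360
  grid <- matrix(0, length(centres), length(centres))
  for (p in seq_len(nrow(points))) {
    for (sx in shifts) {
      for (sy in shifts) {
        gx <- dnorm(centres - (points[p, 1] + sx), sd = bandwidth[1])
        gy <- dnorm(centres - (points[p, 2] + sy), sd = bandwidth[2])
        grid <- grid + outer(gx, gy)
      }
    }
  }
  grid / nrow(points)
}

# ---- shared fixture shortcuts -------------------------------------------

make_test_helix <- function(n = 6L, sequence = NULL, phase = 18,
                            amplitude = 40, noise = 0, seed = 7L, ...) {
  make_helix_mmcif(helix_spec(n_residues = n, sequence = sequence,
                              pucker_phase_deg = phase,
                              pucker_amplitude_deg = amplitude,
                              coordinate_noise_sd = noise, seed = seed, ...))
}

chain_fields <- function(chain) {
  list(structure_id = chain$structure_id, chain_id = chain$chain_id,
       resolution = chain$resolution, release_date = chain$release_date,
       residues = lapply(chain$residues, function(r)
         r[c("index", "auth_label", "nt_code", "is_modified",
             "parent_base", "comp_id", "resolved")]))
}
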