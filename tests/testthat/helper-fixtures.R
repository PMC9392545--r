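# Shared fixtures and independent oracles, built in code at test time.

# Planar unit-spaced grid mesh (nx x ny vertices), triangulated by
# splitting each quad; used for geodesic-distance oracles.
make_grid_mesh <- function(nx, ny) {
  verts <- as.matrix(expand.grid(x = seq_len(nx) - 1,
                                 y = seq_len(ny) - 1))
  verts <- cbind(verts, z = 0)
  idx <- function(i, j) (j - 1) * nx + i
  tris <- list()
  for (j in seq_len(ny - 1)) {
    for (i in seq_len(nx - 1)) {
      tris[[length(tris) + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i, j + 1))
      tris[[length(tris) + 1]] <- c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1))
    }
  }
  new_surface_mesh(verts, do.call(rbind, tris))
}

# Independent shortest-path oracle: plain-R Dijkstra over the mesh edge
# graph (no igraph).
oracle_geodesic <- function(mesh, from, to) {
  tri <- mesh$triangles
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  n <- nrow(mesh$vertices)
  dist <- rep(Inf, n); dist[from] <- 0
  visited <- rep(FALSE, n)
  adj <- lapply(seq_len(n), function(v) {
    i <- which(e[, 1] == v | e[, 2] == v)
    cbind(ifelse(e[i, 1] == v, e[i, 2], e[i, 1]), w[i])
  })
  repeat {
    cand <- which(!visited & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    if (u == to) break
    visited[u] <- TRUE
    nb <- adj[[u]]
    relax <- dist[u] + nb[, 2]
    upd <- relax < dist[nb[, 1]]
    dist[nb[upd, 1]] <- relax[upd]
  }
  dist[to]
}

# Memoized default study simulation (pools precomputed once per session).
default_sim_cache <- local({
  cache <- new.env(parent = emptyenv())
  function(subdivisions = 3) {
    key <- as.character(subdivisions)
    if (is.null(cache[[key]])) {
      cache[[key]] <- default_simulation(subdivisions)
    }
    cache[[key]]
  }
})

# Noiseless per-condition responses for the default study, as a matrix
# vertex x condition (8 conditions + localizer F/H).
noiseless_matrix <- function(sim) {
  labs <- c(condition_table()$label, "F", "H")
  vapply(labs, function(l) noiseless_response(sim$tuning, l, sim$norm),
         numeric(length(sim$tuning$w_face)))
}

# Independent sum-of-squares partition for the balanced two-way
# within-subject design (effects tested against their subject interactions).
oracle_rm_anova <- function(df) {
  gm <- mean(df$value)
  na <- length(unique(df$a)); nb <- length(unique(df$b))
  ns <- length(unique(df$subject))
  m_a <- tapply(df$value, df$a, mean)
  m_b <- tapply(df$value, df$b, mean)
  m_s <- tapply(df$value, df$subject, mean)
  m_ab <- tapply(df$value, list(df$a, df$b), mean)
  m_as <- tapply(df$value, list(df$a, df$subject), mean)
  m_bs <- tapply(df$value, list(df$b, df$subject), mean)
  ss_a <- ns * nb * sum((m_a - gm)^2)
  ss_b <- ns * na * sum((m_b - gm)^2)
  ss_ab <- ns * sum((sweep(sweep(m_ab, 1, m_a), 2, m_b) + gm)^2)
  ss_as <- nb * sum((sweep(sweep(m_as, 1, m_a), 2, m_s) + gm)^2)
  ss_bs <- na * sum((sweep(sweep(m_bs, 1, m_b), 2, m_s) + gm)^2)
  cell <- df$value
  fit_full <- m_ab[cbind(df$a, df$b)] + m_as[cbind(df$a, df$subject)] +
    m_bs[cbind(df$b, df$subject)] - m_a[df$a] - m_b[df$b] -
    m_s[df$subject] + gm
  ss_abs <- sum((cell - fit_full)^2)
  list(
    F_a = (ss_a / (na - 1)) / (ss_as / ((na - 1) * (ns - 1))),
    F_b = (ss_b / (nb - 1)) / (ss_bs / ((nb - 1) * (ns - 1))),
    F_ab = (ss_ab / ((na - 1) * (nb - 1))) /
      (ss_abs / ((na - 1) * (nb - 1) * (ns - 1)))
  )
}
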