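#' Discrete mean-curvature magnitude per mesh vertex
#'
#' Computes the norm of the cotangent-Laplacian mean-curvature normal,
#' `|H_i| = || sum_j (cot a_ij + cot b_ij) (v_i - v_j) || / (4 A_i)`,
#' where `a_ij`, `b_ij` are the angles opposite edge (i, j) and `A_i` is
#' one third of the incident triangle area. On a sphere of radius R the
#' value approaches 1/R; on a plane, 0. Vertices touching degenerate
#' (zero-area) triangles receive the mean of their neighbours' values,
#' with a warning.
#'
#' @param mesh a mesh [sample_domain] (e.g. from [load_mesh()] or
#'   [icosphere()]).
#' @return Non-negative numeric vector of curvature magnitudes, one per
#'   vertex (units 1/length).
#' @export
vertex_curvature <- function(mesh) {
  stopifnot(inherits(mesh, "sample_domain"))
  if (is.null(mesh$faces)) stop("domain has no faces; curvature undefined")
  V <- mesh$points
  F <- mesh$faces
  nv <- nrow(V)
  lap <- matrix(0, nv, 3)       # accumulated cot-weighted edge vectors
  area <- numeric(nv)           # barycentric vertex area
  degen <- logical(nv)

  cot3 <- function(u, w) {      # cotangent of angle between row-vectors u, w
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    rowSums(u * w) / sqrt(rowSums(cr^2))
  }

  i <- F[, 1]; j <- F[, 2]; k <- F[, 3]
  e_ij <- V[j, , drop = FALSE] - V[i, , drop = FALSE]
  e_jk <- V[k, , drop = FALSE] - V[j, , drop = FALSE]
  e_ki <- V[i, , drop = FALSE] - V[k, , drop = FALSE]
  cr <- cbind(e_ij[, 2] * (-e_ki)[, 3] - e_ij[, 3] * (-e_ki)[, 2],
              e_ij[, 3] * (-e_ki)[, 1] - e_ij[, 1] * (-e_ki)[, 3],
              e_ij[, 1] * (-e_ki)[, 2] - e_ij[, 2] * (-e_ki)[, 1])
  tri_area <- 0.5 * sqrt(rowSums(cr^2))
  bad <- tri_area <= .Machine$double.eps * 100
  if (any(bad)) degen[unique(as.vector(F[bad, ]))] <- TRUE

  # cot at vertex k is opposite edge (i, j), etc.
  cot_k <- cot3(-e_jk, e_ki)
  cot_i <- cot3(-e_ki, e_ij)
  cot_j <- cot3(-e_ij, e_jk)
  cot_k[bad] <- 0; cot_i[bad] <- 0; cot_j[bad] <- 0

  # accumulate w * (v_a - v_b) into lap[a, ] and the negation into lap[b, ]
  acc <- function(a, b, w) {
    d <- V[a, , drop = FALSE] - V[b, , drop = FALSE]
    for (c in 1:3) {
      lap[, c] <<- lap[, c] + tab_sum(a, w * d[, c], nv) + tab_sum(b, -w * d[, c], nv)
    }
  }
  acc(i, j, cot_k)
  acc(j, k, cot_i)
  acc(k, i, cot_j)

  a3 <- tri_area / 3
  area <- tab_sum(i, a3, nv) + tab_sum(j, a3, nv) + tab_sum(k, a3, nv)

  H <- sqrt(rowSums(lap^2)) / (4 * pmax(area, .Machine$double.xmin))

  if (any(degen)) {
    warning(sum(degen), " vertices touch degenerate triangles; ",
            "their curvature is neighbourhood-averaged")
    adj <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
    for (vd in which(degen)) {
      nb <- unique(c(adj[adj[, 1] == vd, 2], adj[adj[, 2] == vd, 1]))
      nb <- setdiff(nb, which(degen))
      if (length(nb)) H[vd] <- mean(H[nb])
    }
  }
  H
}

# Sum `w` into bins `idx` over 1..n (dense tabulate-style accumulation).
tab_sum <- function(idx, w, n) {
  out <- numeric(n)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}
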