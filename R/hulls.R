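#' Point cloud for convex-hull volumetrics
#'
#' @param vertices numeric matrix (n x 3) of coordinates in a consistent
#'   length unit; faces are optional and ignored by volume computation.
#' @param faces optional integer matrix of triangle indices
#' @return an object of class `hullMesh`
#' @export
hullMesh <- function(vertices, faces = NULL) {
  v <- as.matrix(vertices)
  if (ncol(v) != 3) stop("vertices must be an n x 3 matrix")
  if (nrow(v) < 4) stop("need at least 4 vertices")
  storage.mode(v) <- "double"
  structure(list(vertices = v, faces = faces), class = "hullMesh")
}

#' @export
print.hullMesh <- function(x, ...) {
  cat("hullMesh with", nrow(x$vertices), "vertices\n")
  invisible(x)
}

# signed distance of points to the plane of face (i,j,k), outward unit normal
.faceNormal <- function(pts, f) {
  a <- pts[f[1], ]; b <- pts[f[2], ]; c <- pts[f[3], ]
  u <- b - a; v <- c - a
  n <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  nn <- sqrt(sum(n^2))
  if (nn == 0) return(NULL)
  list(n = n / nn, d = sum(n / nn * a))
}

#' Volume of the 3D convex hull of a point set
#'
#' Computes the convex hull by the quickhull algorithm and returns its volume
#' as the sum of signed tetrahedra over the hull facets. The result is
#' invariant to interior points and to rigid motion, and scales as s^3 under
#' isotropic scaling by s.
#'
#' @param points a `hullMesh`, or an n x 3 matrix of coordinates
#' @param tol relative tolerance for coplanarity tests (default 1e-9 of the
#'   cloud diameter)
#' @return hull volume (unit^3)
#' @examples
#' cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
#' hullVolume(cube) # 1
#' @export
hullVolume <- function(points, tol = 1e-9) {
  pts <- if (inherits(points, "hullMesh")) points$vertices else as.matrix(points)
  if (ncol(pts) != 3) stop("points must be n x 3")
  if (nrow(pts) < 4) stop("need at least 4 points for a 3D hull")
  storage.mode(pts) <- "double"
  hull <- .quickhull3d(pts, tol = tol)
  vol <- 0
  c0 <- hull$interior
  for (f in hull$faces) {
    a <- pts[f[1], ] - c0; b <- pts[f[2], ] - c0; d <- pts[f[3], ] - c0
    vol <- vol + (a[1] * (b[2] * d[3] - b[3] * d[2]) -
                  a[2] * (b[1] * d[3] - b[3] * d[1]) +
                  a[3] * (b[1] * d[2] - b[2] * d[1])) / 6
  }
  unname(abs(vol))
}

# quickhull in 3D; returns list(faces = list of index triples, interior point)
# Faces are held in preallocated arrays; adjacency is an edge -> face hash so
# the visible region is found by local search rather than a global scan.
.quickhull3d <- function(pts, tol = 1e-9) {
  n <- nrow(pts)
  scale <- max(apply(pts, 2, function(v) diff(range(v))))
  if (scale == 0) stop("degenerate input: all points coincide")
  eps <- tol * scale

  # --- initial simplex from extreme points ---
  ext <- unique(c(apply(pts, 2, which.min), apply(pts, 2, which.max)))
  dmax <- -1; p1 <- p2 <- ext[1]
  for (i in ext) for (j in ext) {
    d <- sum((pts[i, ] - pts[j, ])^2)
    if (d > dmax) { dmax <- d; p1 <- i; p2 <- j }
  }
  if (dmax <= eps^2) stop("degenerate input: all points coincide")
  u <- pts[p2, ] - pts[p1, ]
  rel <- sweep(pts, 2, pts[p1, ])
  cr <- cbind(rel[, 2] * u[3] - rel[, 3] * u[2],
              rel[, 3] * u[1] - rel[, 1] * u[3],
              rel[, 1] * u[2] - rel[, 2] * u[1])
  linedist <- sqrt(rowSums(cr^2)) / sqrt(sum(u^2))
  p3 <- which.max(linedist)
  if (linedist[p3] <= eps) stop("degenerate input: points are collinear")
  fn <- .faceNormal(pts, c(p1, p2, p3))
  planedist <- as.vector(pts %*% fn$n) - fn$d
  p4 <- which.max(abs(planedist))
  if (abs(planedist[p4]) <= eps) stop("degenerate input: points are coplanar")

  interior <- colMeans(pts[c(p1, p2, p3, p4), ])

  cap <- 256L
  faces <- matrix(0L, cap, 3)
  normals <- matrix(0, cap, 3)
  offs <- numeric(cap)
  alive <- logical(cap)
  stamp <- integer(cap)
  outside <- vector("list", cap)
  nf <- 0L
  edge_map <- new.env(hash = TRUE, parent = emptyenv())
  pending <- integer(0)

  grow <- function() {
    cap2 <- 2L * cap
    faces <<- rbind(faces, matrix(0L, cap, 3))
    normals <<- rbind(normals, matrix(0, cap, 3))
    offs <<- c(offs, numeric(cap))
    alive <<- c(alive, logical(cap))
    stamp <<- c(stamp, integer(cap))
    outside <<- c(outside, vector("list", cap))
    cap <<- cap2
  }
  ekey <- function(a, b) paste0(min(a, b), "_", max(a, b))
  register <- function(i) {
    f <- faces[i, ]
    for (e in list(c(f[1], f[2]), c(f[2], f[3]), c(f[3], f[1]))) {
      k <- ekey(e[1], e[2])
      cur <- if (exists(k, envir = edge_map, inherits = FALSE))
        get(k, envir = edge_map) else integer(0)
      assign(k, c(cur, i), envir = edge_map)
    }
  }
  deregister <- function(i) {
    f <- faces[i, ]
    for (e in list(c(f[1], f[2]), c(f[2], f[3]), c(f[3], f[1]))) {
      k <- ekey(e[1], e[2])
      cur <- get(k, envir = edge_map)
      assign(k, cur[cur != i], envir = edge_map)
    }
  }
  neighbour <- function(i, a, b) {
    cur <- get(ekey(a, b), envir = edge_map)
    cur[cur != i][1]
  }

  add_face <- function(a, b, p, cand) {
    fn <- .faceNormal(pts, c(a, b, p))
    if (is.null(fn)) return(integer(0))
    f <- c(a, b, p)
    if (sum(fn$n * interior) - fn$d > 0) { f <- f[c(1, 3, 2)]; fn$n <- -fn$n; fn$d <- -fn$d }
    if (nf + 1L > cap) grow()
    nf <<- nf + 1L
    faces[nf, ] <<- f
    normals[nf, ] <<- fn$n
    offs[nf] <<- fn$d
    alive[nf] <<- TRUE
    if (length(cand)) {
      s <- pts[cand, 1] * fn$n[1] + pts[cand, 2] * fn$n[2] +
           pts[cand, 3] * fn$n[3] - fn$d
      keep <- s > eps
      outside[[nf]] <<- cand[keep]
      if (any(keep)) pending <<- c(pending, nf)
      cand <- cand[!keep]
    } else outside[[nf]] <<- integer(0)
    register(nf)
    cand  # points not claimed by this face
  }

  init <- c(p1, p2, p3, p4)
  cand <- setdiff(seq_len(n), init)
  cand <- add_face(p1, p2, p3, cand)
  cand <- add_face(p1, p2, p4, cand)
  cand <- add_face(p1, p3, p4, cand)
  cand <- add_face(p2, p3, p4, cand)

  iter <- 0L
  while (length(pending)) {
    fi <- pending[length(pending)]
    pending <- pending[-length(pending)]
    if (!alive[fi] || !length(outside[[fi]])) next
    iter <- iter + 1L
    cand <- outside[[fi]]
    s <- pts[cand, 1] * normals[fi, 1] + pts[cand, 2] * normals[fi, 2] +
         pts[cand, 3] * normals[fi, 3] - offs[fi]
    p <- cand[which.max(s)]
    px <- pts[p, ]

    # BFS over adjacent faces to find the visible region and its horizon
    visible <- fi
    stamp[fi] <- iter
    queue <- fi
    horizon_a <- integer(0); horizon_b <- integer(0)
    while (length(queue)) {
      g <- queue[length(queue)]
      queue <- queue[-length(queue)]
      f <- faces[g, ]
      for (e in list(c(f[1], f[2]), c(f[2], f[3]), c(f[3], f[1]))) {
        nb <- neighbour(g, e[1], e[2])
        if (is.na(nb)) next
        if (stamp[nb] == iter) next
        sv <- sum(normals[nb, ] * px) - offs[nb]
        if (sv > eps) {
          stamp[nb] <- iter
          visible <- c(visible, nb)
          queue <- c(queue, nb)
        } else {
          horizon_a <- c(horizon_a, e[1]); horizon_b <- c(horizon_b, e[2])
        }
      }
    }
    # horizon edges may be discovered from both sides; keep each once
    if (length(horizon_a) > 1) {
      k <- paste0(pmin(horizon_a, horizon_b), "_", pmax(horizon_a, horizon_b))
      keep <- !duplicated(k)
      horizon_a <- horizon_a[keep]; horizon_b <- horizon_b[keep]
    }

    cand_all <- unlist(outside[visible])
    cand_all <- cand_all[cand_all != p]
    for (i in visible) { alive[i] <- FALSE; outside[[i]] <- integer(0); deregister(i) }
    for (r in seq_along(horizon_a)) {
      cand_all <- add_face(horizon_a[r], horizon_b[r], p, cand_all)
    }
  }

  list(faces = lapply(which(alive), function(i) faces[i, ]), interior = interior)
}

#' Read mesh vertices from OBJ, PLY (ASCII) or STL (ASCII) files
#'
#' Only vertex coordinates are read -- faces are irrelevant for convex-hull
#' volumetrics. The format is inferred from the file extension unless given.
#'
#' @param file path to the mesh file
#' @param format one of "obj", "ply", "stl" (default: from extension)
#' @return a `hullMesh`
#' @export
readMeshVertices <- function(file, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(file))
  lines <- readLines(file, warn = FALSE)
  v <- switch(format,
    obj = {
      vl <- grep("^v\\s", lines, value = TRUE)
      t(vapply(strsplit(trimws(vl), "\\s+"),
               function(x) as.numeric(x[2:4]), numeric(3)))
    },
    ply = {
      if (!grepl("ascii", lines[2])) stop("only ASCII PLY is supported")
      nv <- as.integer(sub(".*element vertex\\s+", "",
                           grep("element vertex", lines, value = TRUE)[1]))
      start <- which(lines == "end_header")[1] + 1L
      t(vapply(strsplit(trimws(lines[start:(start + nv - 1L)]), "\\s+"),
               function(x) as.numeric(x[1:3]), numeric(3)))
    },
    stl = {
      vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
      m <- t(vapply(strsplit(trimws(vl), "\\s+"),
                    function(x) as.numeric(x[2:4]), numeric(3)))
      unique(m)
    },
    stop("unsupported mesh format: ", format)
  )
  if (is.null(v) || nrow(v) < 4) stop("mesh has fewer than 4 vertices")
  hullMesh(v)
}

#' Write vertices as a minimal OBJ file
#' @param mesh a `hullMesh` or n x 3 matrix
#' @param file output path
#' @export
writeMeshOBJ <- function(mesh, file) {
  v <- if (inherits(mesh, "hullMesh")) mesh$vertices else as.matrix(mesh)
  writeLines(c("# skelevol mesh export",
               sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3])), file)
}
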