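## Neuron morphologies: trees of sections, each section a 3-D polyline with
## per-point diameters.  Coordinates are in micrometres throughout; the soma
## sits at the origin and the main axon descends toward negative z (the
## somato-dendritic axis is the z-axis).

SECTION_KINDS <- c("soma", "axon_unmyelinated", "myelin_internode",
                   "node_of_ranvier", "axon_terminal", "dendrite")

AXONAL_KINDS <- c("axon_unmyelinated", "myelin_internode",
                  "node_of_ranvier", "axon_terminal")

#' Create a morphology section
#'
#' A section is a polyline of 3-D points (micrometres) with per-point
#' diameters.  Non-soma sections need at least two points and a strictly
#' positive arc length; the soma may be a single point (sphere).
#'
#' @param kind one of `soma`, `axon_unmyelinated`, `myelin_internode`,
#'   `node_of_ranvier`, `axon_terminal`, `dendrite`.
#' @param points numeric matrix (n x 3) of coordinates, micrometres.
#' @param diam numeric vector of per-point diameters, micrometres.
#' @param parent integer index of the parent section, or `NA` for the root.
#' @return an object of class `tms_section`.
#' @export
section <- function(kind, points, diam, parent = NA_integer_) {
  kind <- match.arg(kind, SECTION_KINDS)
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    tms_stop("tms_geometry_error", "section points must be an n x 3 matrix")
  if (!all(is.finite(points)))
    tms_stop("tms_geometry_error", "section coordinates must be finite")
  diam <- as.numeric(diam)
  if (length(diam) != nrow(points))
    tms_stop("tms_geometry_error", "one diameter per point is required")
  if (any(!is.finite(diam)) || any(diam <= 0))
    tms_stop("tms_geometry_error", "diameters must be strictly positive")
  if (kind != "soma") {
    if (nrow(points) < 2L)
      tms_stop("tms_geometry_error", "non-soma sections need >= 2 points")
    if (polyline_length(points) <= 0)
      tms_stop("tms_geometry_error", "section arc length must be positive")
  }
  structure(list(kind = kind, points = points, diam = diam,
                 parent = as.integer(parent)),
            class = "tms_section")
}

polyline_length <- function(points) {
  if (nrow(points) < 2L) return(0)
  sum(sqrt(rowSums((points[-1L, , drop = FALSE] -
                      points[-nrow(points), , drop = FALSE])^2)))
}

section_length <- function(s) polyline_length(s$points)

#' Assemble a morphology from sections
#'
#' Sections must be ordered parent-before-child and form a single tree.
#'
#' @param sections list of [section()] objects.
#' @param soma_position 3-vector, micrometres.
#' @param identifier text label for the cell.
#' @return an object of class `tms_morphology`.
#' @export
morphology <- function(sections, soma_position = c(0, 0, 0),
                       identifier = "cell") {
  if (length(sections) < 1L)
    tms_stop("tms_topology_error", "a morphology needs at least one section")
  parents <- vapply(sections, function(s) s$parent, integer(1))
  roots <- which(is.na(parents))
  if (length(roots) != 1L)
    tms_stop("tms_topology_error",
             "exactly one root section required, found %d", length(roots))
  for (i in seq_along(sections)) {
    p <- parents[i]
    if (!is.na(p) && (p < 1L || p >= i))
      tms_stop("tms_topology_error",
               "section %d has invalid parent %d (parents must precede children)",
               i, p)
  }
  structure(list(sections = sections,
                 soma_position = as.numeric(soma_position),
                 identifier = identifier),
            class = "tms_morphology")
}

#' @export
print.tms_morphology <- function(x, ...) {
  kinds <- vapply(x$sections, function(s) s$kind, character(1))
  cat("<tms_morphology> ", x$identifier, "\n", sep = "")
  cat("  sections:", length(x$sections), "\n")
  tab <- table(kinds)
  for (k in names(tab)) cat(sprintf("    %-18s %d\n", k, tab[[k]]))
  ext <- morphology_extent(x)
  cat(sprintf("  z extent: [%.1f, %.1f] um, radial extent: %.1f um\n",
              ext["zmin"], ext["zmax"], ext["radial"]))
  invisible(x)
}

morphology_extent <- function(m) {
  pts <- do.call(rbind, lapply(m$sections, function(s) s$points))
  c(zmin = min(pts[, 3]), zmax = max(pts[, 3]),
    radial = max(sqrt(pts[, 1]^2 + pts[, 2]^2)))
}

#' Myelination parameters
#'
#' Nodes of Ranvier of fixed width separate myelinated internodes whose
#' length-to-diameter ratio is `internode_LD`; terminal myelinated sections
#' use `terminal_LD`.
#'
#' @param node_width node of Ranvier width, micrometres.
#' @param internode_LD internode length/diameter ratio (dimensionless).
#' @param terminal_LD terminal section length/diameter ratio.
#' @return an object of class `tms_myelination_params`.
#' @export
myelination_params <- function(node_width = 1, internode_LD = 100,
                               terminal_LD = 70) {
  stopifnot_scalar_pos(node_width, "node_width")
  stopifnot_scalar_pos(internode_LD, "internode_LD")
  stopifnot_scalar_pos(terminal_LD, "terminal_LD")
  structure(list(node_width = node_width, internode_LD = internode_LD,
                 terminal_LD = terminal_LD),
            class = "tms_myelination_params")
}

## Partition an axonal cable of length L and diameter d into alternating
## node / internode pieces, optionally ending in a terminal of length
## terminal_LD * d (truncated when the cable is shorter).  Boundary
## remainders shorter than a node width are merged into the previous
## internode instead of creating stub sections.
partition_axon <- function(L, d, p, terminal = TRUE,
                           start_with = c("node", "internode")) {
  start_with <- match.arg(start_with)
  w <- p$node_width
  pieces <- list()
  add <- function(kind, len) pieces[[length(pieces) + 1L]] <<- list(kind = kind, len = len)
  term_len <- if (terminal) min(p$terminal_LD * d, L - if (start_with == "node") w else 0) else 0
  if (terminal && term_len <= 0)
    tms_stop("tms_geometry_error",
             "axon of length %g um too short for one node plus terminal", L)
  rem <- L - term_len
  il <- p$internode_LD * d
  first <- TRUE
  while (rem > 1e-9) {
    if (first && start_with == "node") {
      add("node_of_ranvier", min(w, rem)); rem <- rem - min(w, rem)
    } else if (!first) {
      if (rem <= w + 1e-9) {
        ## remainder too short for node + internode: extend last internode
        k <- length(pieces)
        if (pieces[[k]]$kind == "myelin_internode") {
          pieces[[k]]$len <- pieces[[k]]$len + rem
        } else add("myelin_internode", rem)
        rem <- 0
        break
      }
      add("node_of_ranvier", w); rem <- rem - w
    }
    first <- FALSE
    if (rem <= 0) break
    take <- min(il, rem)
    ## avoid leaving a sliver shorter than a node before the terminal
    if (rem - take > 0 && rem - take <= w) take <- rem
    add("myelin_internode", take)
    rem <- rem - take
  }
  if (terminal) add("axon_terminal", term_len)
  pieces
}

## Interpolate a position and diameter at arc-length s along a polyline.
polyline_at <- function(points, diam, s) {
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  s <- min(max(s, 0), cum[length(cum)])
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- min(i, length(seg))
  f <- if (seg[i] > 0) (s - cum[i]) / seg[i] else 0
  list(pos = points[i, ] + f * (points[i + 1L, ] - points[i, ]),
       diam = diam[i] + f * (diam[i + 1L] - diam[i]))
}

## Split a polyline at interior arc lengths `breaks` (strictly increasing,
## inside (0, L)); returns a list of (points, diam) pieces sharing boundary
## points, so total arc length is conserved exactly.
split_polyline <- function(points, diam, breaks) {
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  edges <- c(0, breaks, L)
  out <- vector("list", length(edges) - 1L)
  for (k in seq_len(length(edges) - 1L)) {
    a <- edges[k]; b <- edges[k + 1L]
    inner <- which(cum > a + 1e-9 & cum < b - 1e-9)
    pa <- polyline_at(points, diam, a)
    pb <- polyline_at(points, diam, b)
    pts <- rbind(pa$pos,
                 points[inner, , drop = FALSE],
                 pb$pos)
    dm <- c(pa$diam, diam[inner], pb$diam)
    out[[k]] <- list(points = pts, diam = dm)
  }
  out
}

#' Generate a myelinated ball-and-stick morphology
#'
#' A spherical soma at the origin with a straight axon descending along the
#' negative z-axis.  The axon starts with a node of Ranvier at the soma,
#' alternates internodes and nodes, and ends in a myelinated terminal of
#' length `terminal_LD * diameter` (truncated when the axon is shorter).
#'
#' @param axon_length total axon length, micrometres.
#' @param axon_diameter axon diameter, micrometres.
#' @param myelin a [myelination_params()] object.
#' @param soma_diameter soma diameter, micrometres.
#' @return a `tms_morphology`.
#' @export
generate_ball_and_stick <- function(axon_length, axon_diameter,
                                    myelin = myelination_params(),
                                    soma_diameter = 20) {
  if (!is.numeric(axon_length) || length(axon_length) != 1 ||
      !is.finite(axon_length) || axon_length <= 0)
    tms_stop("tms_geometry_error", "axon_length must be positive")
  stopifnot_scalar_pos(axon_diameter, "axon_diameter")
  stopifnot_scalar_pos(soma_diameter, "soma_diameter")
  pieces <- partition_axon(axon_length, axon_diameter, myelin,
                           terminal = TRUE, start_with = "node")
  secs <- list(section("soma", matrix(c(0, 0, 0), 1), soma_diameter, NA))
  z <- 0
  parent <- 1L
  for (p in pieces) {
    z2 <- z - p$len
    secs[[length(secs) + 1L]] <-
      section(p$kind, rbind(c(0, 0, z), c(0, 0, z2)),
              rep(axon_diameter, 2), parent)
    parent <- length(secs)
    z <- z2
  }
  morphology(secs, identifier = sprintf("ball_and_stick_l%g_d%g",
                                        axon_length, axon_diameter))
}

#' Myelinate the axonal arbor of a morphology
#'
#' Replaces each `axon_unmyelinated` section by an alternating sequence of
#' myelinated internodes (length/diameter = `internode_LD`) and nodes of
#' Ranvier (`node_width` wide), conserving arc length.  Sections without
#' axonal children end in a myelinated terminal of length
#' `terminal_LD * diameter`.  The first `initial_segment` micrometres of
#' soma-attached axon sections are left unmyelinated (axon initial segment).
#'
#' @param m a `tms_morphology`.
#' @param p a [myelination_params()] object.
#' @param initial_segment unmyelinated initial segment length, micrometres.
#' @return a `tms_morphology` with myelinated axon; warns and returns the
#'   input unchanged if it has no axonal sections.
#' @export
myelinate_axon <- function(m, p = myelination_params(), initial_segment = 30) {
  kinds <- vapply(m$sections, function(s) s$kind, character(1))
  idx_axon <- which(kinds == "axon_unmyelinated")
  if (length(idx_axon) == 0L) {
    tms_warn("tms_no_axon_warning", "morphology has no unmyelinated axon; unchanged")
    return(m)
  }
  old_parents <- vapply(m$sections, function(s) s$parent, integer(1))
  has_axonal_child <- function(i)
    any(old_parents == i & kinds %in% AXONAL_KINDS, na.rm = TRUE)

  new_secs <- list()
  ## maps old section index -> (first new index, last new index)
  first_new <- integer(length(m$sections))
  last_new <- integer(length(m$sections))
  for (i in seq_along(m$sections)) {
    s <- m$sections[[i]]
    np <- if (is.na(s$parent)) NA_integer_ else last_new[s$parent]
    if (kinds[i] != "axon_unmyelinated") {
      new_secs[[length(new_secs) + 1L]] <-
        section(s$kind, s$points, s$diam, np)
      first_new[i] <- last_new[i] <- length(new_secs)
      next
    }
    L <- section_length(s)
    d <- mean(s$diam)
    terminal <- !has_axonal_child(i)
    ais <- if (!is.na(s$parent) && kinds[s$parent] == "soma")
      min(initial_segment, if (terminal) max(L - p$terminal_LD * d, 0) else L)
    else 0
    plan <- list()
    if (ais > 0) plan[[1L]] <- list(kind = "axon_unmyelinated", len = ais)
    rem <- L - ais
    if (rem > 1e-9) {
      pieces <- tryCatch(
        partition_axon(rem, d, p, terminal = terminal,
                       start_with = "internode"),
        tms_geometry_error = function(e)
          list(list(kind = if (terminal) "axon_terminal" else "axon_unmyelinated",
                    len = rem)))
      plan <- c(plan, pieces)
    }
    lens <- vapply(plan, function(x) x$len, numeric(1))
    breaks <- cumsum(lens)[-length(lens)]
    geo <- split_polyline(s$points, s$diam, breaks)
    for (k in seq_along(plan)) {
      new_secs[[length(new_secs) + 1L]] <-
        section(plan[[k]]$kind, geo[[k]]$points, geo[[k]]$diam, np)
      np <- length(new_secs)
      if (k == 1L) first_new[i] <- np
    }
    last_new[i] <- np
  }
  morphology(new_secs, m$soma_position, m$identifier)
}

#' Per-part scaling of a morphology
#'
#' Multiplies lengths and/or diameters of named parts (`soma`, `axon`,
#' `dendrite`).  Length scaling rescales each section about its attachment
#' point and translates its subtree accordingly; topology is unchanged.
#' Defaults are the identity (no particular species-conversion factors
#' are assumed).
#'
#' @param m a `tms_morphology`.
#' @param factors named list; recognised names are `soma_diameter`,
#'   `axon_diameter`, `axon_length`, `dendrite_diameter`, `dendrite_length`.
#' @return the scaled `tms_morphology`.
#' @export
apply_scaling <- function(m, factors = list()) {
  known <- c("soma_diameter", "axon_diameter", "axon_length",
             "dendrite_diameter", "dendrite_length")
  bad <- setdiff(names(factors), known)
  if (length(bad))
    tms_stop("tms_config_error", "unknown scaling factor(s): %s",
             paste(bad, collapse = ", "))
  f <- function(nm) {
    v <- factors[[nm]] %||% 1
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      tms_stop("tms_config_error", "scaling factor '%s' must be positive", nm)
    v
  }
  part_of <- function(kind) {
    if (kind == "soma") "soma"
    else if (kind %in% AXONAL_KINDS) "axon"
    else "dendrite"
  }
  secs <- m$sections
  new_pts <- vector("list", length(secs))
  for (i in seq_along(secs)) {
    s <- secs[[i]]
    part <- part_of(s$kind)
    flen <- if (part == "axon") f("axon_length")
    else if (part == "dendrite") f("dendrite_length") else 1
    fd <- if (part == "soma") f("soma_diameter")
    else if (part == "axon") f("axon_diameter") else f("dendrite_diameter")
    attach_new <- if (is.na(s$parent)) s$points[1L, ]
    else new_pts[[s$parent]][nrow(new_pts[[s$parent]]), ]
    base <- s$points[1L, ]
    pts <- sweep(sweep(s$points, 2, base) * flen, 2, attach_new, "+")
    new_pts[[i]] <- pts
    secs[[i]] <- section(s$kind, pts, s$diam * fd, s$parent)
  }
  morphology(secs, m$soma_position, m$identifier)
}

## ---- synthetic population generator -------------------------------------

unit_vec <- function(polar_deg, azim_deg) {
  th <- deg2rad(polar_deg); ph <- deg2rad(azim_deg)
  c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}

#' Generate a seeded synthetic population of branched cortical cells
#'
#' Stand-ins for reconstructed cortical neurons: each cell has a spherical
#' soma at the origin, a main myelinated axon descending along negative z
#' with randomized oblique/horizontal collaterals ending in myelinated
#' terminals, and passive dendrites.  `pyramidal_like` cells carry an
#' apical-trunk-like vertical dendrite and are taller than wide;
#' `basket_like` cells are more isotropic.  Generation is bitwise
#' reproducible for a fixed seed.
#'
#' @param n_cells number of cells (>= 1).
#' @param archetype `"pyramidal_like"` or `"basket_like"`.
#' @param seed integer seed fixing the random stream.
#' @param myelin a [myelination_params()] object.
#' @param initial_segment unmyelinated axon initial segment, micrometres.
#' @param axon_length,axon_diameter mean main-axon geometry, micrometres.
#' @param n_collaterals mean number of axon collaterals.
#' @param main_axon_cut if `TRUE` (default for `pyramidal_like`), the main
#'   descending axon does not end in an excitable terminal: its distal
#'   section is kept as passive myelin, emulating a projection axon severed
#'   at the white-matter boundary, so activation sites live on the
#'   collateral terminals.
#' @return list of `tms_morphology` objects.
#' @export
generate_synthetic_population <- function(n_cells, archetype = c("pyramidal_like",
                                                                 "basket_like"),
                                          seed = 1L,
                                          myelin = myelination_params(),
                                          initial_segment = 30,
                                          axon_length = NULL,
                                          axon_diameter = 1.5,
                                          n_collaterals = 7L,
                                          main_axon_cut = NULL) {
  if (!is.numeric(n_cells) || length(n_cells) != 1 || n_cells < 1)
    tms_stop("tms_config_error", "n_cells must be >= 1")
  if (is.character(archetype) &&
      !archetype[1L] %in% c("pyramidal_like", "basket_like"))
    tms_stop("tms_config_error", "unknown archetype '%s'", archetype[1L])
  archetype <- match.arg(archetype)
  pyramidal <- archetype == "pyramidal_like"
  axon_length <- axon_length %||% if (pyramidal) 900 else 500
  main_axon_cut <- main_axon_cut %||% pyramidal
  with_seed(seed, {
    lapply(seq_len(n_cells), function(ci) {
      soma_d <- if (pyramidal) 16 else 12
      secs <- list(section("soma", matrix(c(0, 0, 0), 1), soma_d, NA))
      ## axonal trunks: pyramidal cells have one main descending axon;
      ## basket cells ramify from the soma in both directions, so they get
      ## a descending and an ascending trunk
      trunk_spec <- if (pyramidal) list(c(1, -1))
      else list(c(1, -1), c(0.7, 1))
      ncol_i <- max(2L, rpois_like(n_collaterals))
      branch_parent <- integer(0)
      for (tr in trunk_spec) {
        La <- axon_length * tr[1] * runif(1, 0.85, 1.15)
        nseg <- max(2L, ceiling(La / 150))
        zs <- seq(0, tr[2] * La, length.out = nseg + 1L)
        jit <- cbind(c(0, cumsum(rnorm(nseg, 0, 8))),
                     c(0, cumsum(rnorm(nseg, 0, 8))), zs)
        ## collateral origins at random arc positions along the trunk
        ntr <- max(1L, round(ncol_i * tr[1] / sum(vapply(trunk_spec, `[`,
                                                         numeric(1), 1))))
        br_s <- sort(runif(ntr, 0.2, 0.95)) * La
        pieces <- split_polyline(jit, rep(axon_diameter, nrow(jit)), br_s)
        parent <- 1L
        for (k in seq_along(pieces)) {
          secs[[length(secs) + 1L]] <- section("axon_unmyelinated",
                                               pieces[[k]]$points,
                                               pieces[[k]]$diam, parent)
          parent <- length(secs)
          if (k <= ntr) branch_parent <- c(branch_parent, parent)
        }
      }
      ## collaterals cover upward (cortico-cortical), horizontal and
      ## oblique-descending directions (area-uniform polar draw) so that
      ## activation sites exist for every field orientation
      for (bp in branch_parent) {
        pol <- acos(runif(1, cos(deg2rad(160)), cos(deg2rad(20)))) * 180 / pi
        az <- runif(1, 0, 360)
        len <- runif(1, 250, if (pyramidal) 600 else 450)
        d <- axon_diameter * runif(1, 0.6, 0.9)
        p0 <- secs[[bp]]$points
        p0 <- p0[nrow(p0), ]
        dirv <- unit_vec(pol, az)
        pts <- rbind(p0, p0 + dirv * len * 0.5, p0 + dirv * len)
        secs[[length(secs) + 1L]] <- section("axon_unmyelinated", pts,
                                             rep(d, 3), bp)
        ## each collateral forks into two daughter branches whose
        ## directions decorrelate from the parent, multiplying the
        ## terminal directions available for activation
        stem <- length(secs)
        for (j in 1:2) {
          pol2 <- acos(runif(1, cos(deg2rad(170)), cos(deg2rad(10)))) * 180 / pi
          az2 <- runif(1, 0, 360)
          len2 <- runif(1, 150, 300)
          d2 <- d * runif(1, 0.7, 0.95)
          tip <- pts[3, ]
          dv2 <- unit_vec(pol2, az2)
          pts2 <- rbind(tip, tip + dv2 * len2 * 0.5, tip + dv2 * len2)
          secs[[length(secs) + 1L]] <- section("axon_unmyelinated", pts2,
                                               rep(d2, 3), stem)
        }
      }
      ## dendrites (passive)
      add_dendrite <- function(pol, az, len, d) {
        dirv <- unit_vec(pol, az)
        pts <- rbind(c(0, 0, 0), dirv * len * 0.5, dirv * len)
        secs[[length(secs) + 1L]] <<- section("dendrite", pts, rep(d, 3), 1L)
      }
      if (pyramidal) {
        add_dendrite(runif(1, 0, 8), runif(1, 0, 360),
                     runif(1, 500, 700), 3)
        for (j in 1:2)
          add_dendrite(runif(1, 110, 150), runif(1, 0, 360),
                       runif(1, 150, 250), 2)
      } else {
        for (j in 1:4)
          add_dendrite(runif(1, 30, 150), runif(1, 0, 360),
                       runif(1, 150, 250), 2)
      }
      m <- morphology(secs,
                      identifier = sprintf("%s_%03d", archetype, ci))
      m <- myelinate_axon(m, myelin, initial_segment = initial_segment)
      if (main_axon_cut) {
        ## the deepest terminal belongs to the main descending axon: keep
        ## it passive (severed projection axon, not a sealed ending)
        term <- which(vapply(m$sections, function(s)
          s$kind == "axon_terminal", logical(1)))
        if (length(term)) {
          zmin <- vapply(term, function(i) min(m$sections[[i]]$points[, 3]),
                         numeric(1))
          deepest <- term[which.min(zmin)]
          m$sections[[deepest]]$kind <- "myelin_internode"
        }
      }
      m
    })
  })
}

## small helper: integer jitter around a mean without tying to rpois's
## stream signature (keeps the draw count per cell fixed)
rpois_like <- function(mean) {
  round(mean + runif(1, -1, 1))
}
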