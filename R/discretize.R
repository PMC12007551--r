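## Discretization of a morphology into electrical compartments.  Each
## section is cut into equal-arc pieces no longer than `max_len`; nodes of
## Ranvier, terminals and unmyelinated axon are electrically active,
## internodes are passive with reduced membrane conductance/capacitance,
## soma and dendrites are passive with leak.

MEMBRANE_ROLES <- c(soma = "passive_soma_dendrite",
                    dendrite = "passive_soma_dendrite",
                    axon_unmyelinated = "active_node",
                    node_of_ranvier = "active_node",
                    axon_terminal = "active_node",
                    myelin_internode = "passive_myelin")

#' Discretize a morphology into a compartment model
#'
#' @param m a `tms_morphology`.
#' @param max_len maximum compartment length, micrometres (default 20).
#' @return an object of class `tms_compartment_model` with per-compartment
#'   centers (micrometres), endpoints, lengths, diameters, section kinds,
#'   membrane roles, and a parent index defining the tree (NA at the root).
#' @export
discretize <- function(m, max_len = 20) {
  stopifnot_scalar_pos(max_len, "max_len")
  centers <- list(); ep1 <- list(); ep2 <- list()
  len <- c(); diam <- c(); kind <- c(); sec_id <- c()
  parent <- c(); sphere <- c()
  last_comp <- integer(length(m$sections))
  idx <- 0L
  for (si in seq_along(m$sections)) {
    s <- m$sections[[si]]
    pcomp <- if (is.na(s$parent)) NA_integer_ else last_comp[s$parent]
    if (s$kind == "soma" && nrow(s$points) == 1L) {
      idx <- idx + 1L
      centers[[idx]] <- s$points[1L, ]
      ep1[[idx]] <- s$points[1L, ]; ep2[[idx]] <- s$points[1L, ]
      len[idx] <- s$diam[1L]        # effective axial length of the sphere
      diam[idx] <- s$diam[1L]
      kind[idx] <- s$kind; sec_id[idx] <- si
      parent[idx] <- pcomp; sphere[idx] <- TRUE
      last_comp[si] <- idx
      next
    }
    L <- section_length(s)
    nc <- max(1L, ceiling(L / max_len - 1e-9))
    bounds <- seq(0, L, length.out = nc + 1L)
    for (k in seq_len(nc)) {
      idx <- idx + 1L
      a <- polyline_at(s$points, s$diam, bounds[k])
      b <- polyline_at(s$points, s$diam, bounds[k + 1L])
      cmid <- polyline_at(s$points, s$diam, (bounds[k] + bounds[k + 1L]) / 2)
      centers[[idx]] <- cmid$pos
      ep1[[idx]] <- a$pos; ep2[[idx]] <- b$pos
      len[idx] <- L / nc
      diam[idx] <- cmid$diam
      kind[idx] <- s$kind; sec_id[idx] <- si
      parent[idx] <- pcomp; sphere[idx] <- FALSE
      pcomp <- idx
    }
    last_comp[si] <- idx
  }
  structure(list(center = unname(do.call(rbind, centers)),
                 ep1 = unname(do.call(rbind, ep1)),
                 ep2 = unname(do.call(rbind, ep2)),
                 length = len, diam = diam, kind = kind,
                 role = unname(MEMBRANE_ROLES[kind]),
                 section = sec_id,
                 parent = as.integer(parent),
                 is_sphere = sphere,
                 cell_id = m$identifier),
            class = "tms_compartment_model")
}

#' @export
print.tms_compartment_model <- function(x, ...) {
  cat("<tms_compartment_model> ", x$cell_id, "\n", sep = "")
  cat("  compartments:", length(x$length), "\n")
  tab <- table(x$role)
  for (k in names(tab)) cat(sprintf("    %-22s %d\n", k, tab[[k]]))
  cat(sprintf("  total cable length: %.1f um\n", sum(x$length[!x$is_sphere])))
  invisible(x)
}

n_compartments <- function(cm) length(cm$length)
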