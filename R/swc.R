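## SWC interchange (7 columns: id type x y z radius parent).  Standard type
## codes 1 soma, 2 axon, 3/4 dendrite are used; because SWC has no myelin
## vocabulary, three custom codes extend it:
##   11 = myelin internode, 12 = node of Ranvier, 13 = myelinated axon terminal.
## Child sections attach at their parent's last written record; on reading,
## that record's coordinates are re-added as the section's first point, with
## the child's own first diameter (so diameters never bleed across kinds).

SWC_CODES <- c(soma = 1, axon_unmyelinated = 2, dendrite = 3,
               myelin_internode = 11, node_of_ranvier = 12,
               axon_terminal = 13)

swc_kind_from_code <- function(code) {
  if (code == 4) return("dendrite")   # apical dendrite maps to dendrite
  k <- names(SWC_CODES)[match(code, SWC_CODES)]
  if (is.na(k)) NA_character_ else k
}

#' Read a morphology from an SWC file
#'
#' @param path path to a whitespace-separated 7-column SWC file.
#' @return a `tms_morphology`.
#' @export
load_swc <- function(path) {
  if (!file.exists(path))
    tms_stop("tms_parse_error", "SWC file '%s' does not exist", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  ln <- which(keep)
  if (!length(ln)) tms_stop("tms_parse_error", "SWC file '%s' has no records", path)
  n <- length(ln)
  rec <- matrix(NA_real_, n, 7)
  for (i in seq_len(n)) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[ln[i]]), "\\s+")[[1]]))
    if (length(f) != 7L || any(is.na(f)))
      tms_stop("tms_parse_error", "malformed SWC record at line %d of '%s'",
               ln[i], path)
    rec[i, ] <- f
  }
  id <- as.integer(rec[, 1]); type <- as.integer(rec[, 2])
  xyz <- rec[, 3:5, drop = FALSE]; radius <- rec[, 6]
  parent <- as.integer(rec[, 7])
  if (anyDuplicated(id))
    tms_stop("tms_parse_error", "duplicate record ids in '%s'", path)
  if (any(radius <= 0))
    tms_stop("tms_parse_error", "non-positive radius in '%s'", path)
  idx <- seq_len(n); names(idx) <- id
  pidx <- integer(n)
  for (i in seq_len(n)) {
    if (parent[i] == -1L) { pidx[i] <- NA_integer_; next }
    j <- idx[as.character(parent[i])]
    if (is.na(j) || j >= i)
      tms_stop("tms_topology_error",
               "record %d (line %d) references undefined or later parent %d",
               id[i], ln[i], parent[i])
    pidx[i] <- j
  }
  if (sum(is.na(pidx)) != 1L)
    tms_stop("tms_topology_error", "SWC file must have exactly one root record")

  kind <- vapply(type, swc_kind_from_code, character(1))
  if (anyNA(kind)) {
    tms_warn("tms_swc_code_warning",
             "unknown SWC type code(s) %s treated as dendrite",
             paste(unique(type[is.na(kind)]), collapse = ", "))
    kind[is.na(kind)] <- "dendrite"
  }
  nchild <- tabulate(pidx[!is.na(pidx)], n)

  ## section starts: root, children of branch points, kind changes, and
  ## children of the soma sphere
  is_start <- is.na(pidx)
  for (i in which(!is.na(pidx))) {
    p <- pidx[i]
    if (nchild[p] > 1L || kind[i] != kind[p] || kind[p] == "soma")
      is_start[i] <- TRUE
  }
  secs <- list()
  sec_of_record <- integer(n)
  starts <- which(is_start)
  ## process in record order: parents precede children, so parent sections
  ## are always built first
  for (s0 in starts) {
    chain <- s0
    repeat {
      kids <- which(pidx == tail(chain, 1L))
      kids <- kids[!is_start[kids]]
      if (length(kids) != 1L) break
      chain <- c(chain, kids)
    }
    p <- pidx[s0]
    if (is.na(p)) {
      pts <- xyz[chain, , drop = FALSE]
      dm <- 2 * radius[chain]
      parent_sec <- NA_integer_
    } else {
      pts <- rbind(xyz[p, ], xyz[chain, , drop = FALSE])
      dm <- c(2 * radius[s0], 2 * radius[chain])
      parent_sec <- sec_of_record[p]
    }
    secs[[length(secs) + 1L]] <- section(kind[s0], pts, dm, parent_sec)
    sec_of_record[chain] <- length(secs)
  }
  soma_pos <- if (kind[is.na(pidx)] == "soma") xyz[is.na(pidx), ] else c(0, 0, 0)
  morphology(secs, soma_position = soma_pos,
             identifier = sub("\\.swc$", "", basename(path)))
}

#' Write a morphology to an SWC file
#'
#' @param m a `tms_morphology`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_swc <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# SWC export (tmsresponse)",
               "# type codes: 1 soma, 2 axon, 3 dendrite,",
               "#   11 myelin internode, 12 node of Ranvier, 13 axon terminal",
               "# id type x y z radius parent"), con)
  id <- 0L
  last_id <- integer(length(m$sections))
  out <- character(0)
  fmt <- function(i, type, p3, r, par)
    sprintf("%d %d %.9g %.9g %.9g %.9g %d", i, type, p3[1], p3[2], p3[3], r, par)
  for (si in seq_along(m$sections)) {
    s <- m$sections[[si]]
    code <- SWC_CODES[[s$kind]]
    if (is.na(s$parent)) {
      rows <- seq_len(nrow(s$points))
      par <- -1L
    } else {
      rows <- seq_len(nrow(s$points))[-1L]   # skip attachment duplicate
      par <- last_id[s$parent]
    }
    for (r in rows) {
      id <- id + 1L
      out[length(out) + 1L] <- fmt(id, code, s$points[r, ], s$diam[r] / 2, par)
      par <- id
    }
    last_id[si] <- id
  }
  writeLines(out, con)
  invisible(path)
}
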