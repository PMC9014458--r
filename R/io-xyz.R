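#' Read a multi-frame extended XYZ file as an ensemble
#'
#' Each frame is an atom-count line, a comment line, then one line per atom
#' (`element x y z`). The comment line may carry space-separated `key=value`
#' metadata; recognised keys are `label`, `charge`, `fragments` (comma list
#' of per-atom fragment ids) and `sites` (sparse `index:TAG` comma list,
#' 1-based). Unknown keys are preserved verbatim and written back by
#' [write_multiframe_xyz()]. Frames without `fragments` metadata get their
#' water fragments inferred from connectivity (see [infer_fragments()]).
#'
#' @param path Path to an existing file.
#' @param temperature Ensemble temperature (K) attached to the result.
#' @return An [ensemble()] preserving frame order.
#' @export
read_multiframe_xyz <- function(path, temperature = 298.15) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  conformers <- list()
  i <- 1L
  frame <- 0L
  n_atoms_first <- NA_integer_
  while (i <= length(lines)) {
    if (grepl("^\\s*$", lines[i]) && i == length(lines)) break
    frame <- frame + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n <= 0) {
      stop("malformed atom count at line ", i, ": '", lines[i], "'",
        call. = FALSE
      )
    }
    if (is.na(n_atoms_first)) {
      n_atoms_first <- n
    } else if (n != n_atoms_first) {
      stop("inconsistent atom counts across frames (frame ", frame, " has ",
        n, ", expected ", n_atoms_first, ")",
        call. = FALSE
      )
    }
    if (i + 1L + n > length(lines)) {
      stop("truncated frame ", frame, " starting at line ", i, call. = FALSE)
    }
    meta <- parse_xyz_comment(lines[i + 1L])
    atom_lines <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(atom_lines), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) < 4)
    if (length(bad) > 0) {
      stop("malformed atom line at line ", i + 1L + bad[1], call. = FALSE)
    }
    atoms <- tibble::tibble(
      element = vapply(parts, `[`, character(1), 1),
      x = as.numeric(vapply(parts, `[`, character(1), 2)),
      y = as.numeric(vapply(parts, `[`, character(1), 3)),
      z = as.numeric(vapply(parts, `[`, character(1), 4))
    )
    if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z)) {
      stop("non-numeric coordinate in frame ", frame, call. = FALSE)
    }
    if (!is.null(meta$fragments)) {
      if (length(meta$fragments) != n) {
        stop("fragments metadata length mismatch in frame ", frame,
          call. = FALSE
        )
      }
      atoms$fragment_id <- meta$fragments
    } else {
      atoms$fragment_id <- infer_fragments(atoms)
    }
    atoms$site_tag <- "OTHER"
    if (!is.null(meta$sites)) {
      atoms$site_tag[meta$sites$index] <- meta$sites$tag
    }
    label <- if (!is.null(meta$label)) meta$label else sprintf("frame_%04d", frame)
    charge <- if (!is.null(meta$charge)) meta$charge else 0L
    conf <- conformer(atoms, label = label, total_charge = charge)
    if (!is.null(meta$extra)) attr(conf, "xyz_extra") <- meta$extra
    conformers[[frame]] <- conf
    i <- i + 2L + n
    while (i <= length(lines) && grepl("^\\s*$", lines[i])) i <- i + 1L
  }
  if (frame == 0L) stop("no frames found in ", path, call. = FALSE)
  ensemble(conformers, temperature = temperature)
}

parse_xyz_comment <- function(line) {
  out <- list(extra = NULL)
  tokens <- strsplit(trimws(line), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  extras <- character(0)
  for (tok in tokens) {
    if (!grepl("=", tok, fixed = TRUE)) {
      extras <- c(extras, tok)
      next
    }
    key <- sub("=.*$", "", tok)
    val <- sub("^[^=]*=", "", tok)
    if (key == "label") {
      out$label <- val
    } else if (key == "charge") {
      out$charge <- as.integer(val)
    } else if (key == "fragments") {
      out$fragments <- as.integer(strsplit(val, ",", fixed = TRUE)[[1]])
    } else if (key == "sites") {
      pairs <- strsplit(strsplit(val, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
      out$sites <- list(
        index = as.integer(vapply(pairs, `[`, character(1), 1)),
        tag = vapply(pairs, `[`, character(1), 2)
      )
    } else {
      extras <- c(extras, tok)
    }
  }
  if (length(extras) > 0) out$extra <- paste(extras, collapse = " ")
  out
}

#' Infer fragment assignments from covalent connectivity
#'
#' Connected components under an interatomic distance cutoff of 1.7 Angstrom
#' are computed; components whose composition is exactly OH2 become water
#' fragments numbered by order of first appearance in the file, and all other
#' atoms form the solute (fragment 0).
#'
#' @param atoms Atom tibble with `element`, `x`, `y`, `z`.
#' @param cutoff Covalent-bond distance cutoff in Angstrom.
#' @return Integer vector of fragment ids, one per atom.
#' @export
infer_fragments <- function(atoms, cutoff = 1.7) {
  n <- nrow(atoms)
  m <- as.matrix(atoms[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(m))
  adj <- d <= cutoff
  diag(adj) <- FALSE
  comp <- integer(n) # 0 = unvisited
  ncomp <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    stack <- s
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- ncomp
      nb <- which(adj[v, ] & comp == 0L)
      stack <- c(stack, nb)
    }
  }
  frag <- integer(n)
  next_water <- 1L
  for (k in seq_len(ncomp)) {
    idx <- which(comp == k)
    comp_elems <- sort(atoms$element[idx])
    if (identical(comp_elems, c("H", "H", "O"))) {
      frag[idx] <- next_water
      next_water <- next_water + 1L
    } else {
      frag[idx] <- 0L
    }
  }
  frag
}

#' Write an ensemble as multi-frame extended XYZ
#'
#' The comment line of each frame carries `label=`, `charge=`, `fragments=`
#' and, for atoms tagged with a named site, `sites=` metadata so the file
#' round-trips through [read_multiframe_xyz()]. Coordinates are written with
#' six decimals and LF line endings.
#'
#' @param ens An [ensemble()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multiframe_xyz <- function(ens, path) {
  stopifnot(inherits(ens, "ensemble"))
  labels <- vapply(ens, function(c) c$label, character(1))
  if (anyDuplicated(labels)) {
    stop("duplicate conformer labels: ",
      paste(unique(labels[duplicated(labels)]), collapse = ", "),
      call. = FALSE
    )
  }
  out <- character(0)
  for (conf in ens) {
    atoms <- conf$atoms
    meta <- sprintf(
      "label=%s charge=%d fragments=%s",
      conf$label, conf$total_charge,
      paste(atoms$fragment_id, collapse = ",")
    )
    tagged <- which(atoms$site_tag != "OTHER")
    if (length(tagged) > 0) {
      meta <- paste0(
        meta, " sites=",
        paste(sprintf("%d:%s", tagged, atoms$site_tag[tagged]), collapse = ",")
      )
    }
    extra <- attr(conf, "xyz_extra")
    if (!is.null(extra)) meta <- paste(meta, extra)
    out <- c(
      out,
      as.character(nrow(atoms)),
      meta,
      sprintf("%-2s %12.6f %12.6f %12.6f", atoms$element, atoms$x, atoms$y, atoms$z)
    )
  }
  con <- file(path, open = "wb") # LF endings on every platform
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}

#' Read a single-model PDB file as a solute conformer
#'
#' Thin wrapper over `bio3d::read.pdb()` for solute templates; all atoms are
#' assigned to fragment 0 and tagged `OTHER`.
#'
#' @param path Path to a PDB file.
#' @param label Conformer label.
#' @param total_charge Total charge (e).
#' @return A [conformer()].
#' @export
read_pdb_solute <- function(path, label = "solute", total_charge = 0L) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("read_pdb_solute requires the bio3d package", call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path)
  el <- pdb$atom$elesy
  if (is.null(el) || all(is.na(el)) || all(!nzchar(trimws(el)))) {
    el <- substr(trimws(pdb$atom$elety), 1, 1)
  }
  atoms <- tibble::tibble(
    element = trimws(el),
    x = pdb$atom$x, y = pdb$atom$y, z = pdb$atom$z,
    fragment_id = 0L
  )
  conformer(atoms, label = label, total_charge = total_charge)
}
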