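#' Molecular conformer: a labelled geometry with fragment assignments
#'
#' A conformer is a tibble of atoms plus metadata. The atom table has one row
#' per atom with columns `element` (chemical symbol), `x`, `y`, `z`
#' (Cartesian coordinates, Angstrom), `fragment_id` (0 = solute, k >= 1 =
#' k-th water molecule), `site_tag` (one of `PHOSPHATE_O`, `AMINE_N10`,
#' `PURINE_O11`, `PURINE_RING_N`, `RIBOSE_OH`, `OTHER`) and optionally
#' `charge` (partial charge, e; used by the toy energy model).
#'
#' Water fragments must consist of exactly one oxygen and two hydrogens.
#'
#' @param atoms Data frame of atoms (see above). `site_tag` and `charge` are
#'   optional and default to `"OTHER"` and `0`.
#' @param label Character conformer label, unique within an ensemble.
#' @param total_charge Integer total charge in elementary charges.
#' @return An object of class `conformer`: a list with elements `atoms`
#'   (tibble), `label`, `total_charge` and `n_waters`.
#' @examples
#' w <- water_template()
#' conformer(w, label = "w1", total_charge = 0)
#' @export
conformer <- function(atoms, label = "conf", total_charge = 0L) {
  atoms <- tibble::as_tibble(atoms)
  required <- c("element", "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    stop("conformer atoms lack column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"fragment_id" %in% names(atoms)) atoms$fragment_id <- 0L
  if (!"site_tag" %in% names(atoms)) atoms$site_tag <- "OTHER"
  if (!"charge" %in% names(atoms)) atoms$charge <- 0
  atoms$fragment_id <- as.integer(atoms$fragment_id)
  bad_tag <- setdiff(unique(atoms$site_tag), ATOM_SITE_TAGS)
  if (length(bad_tag) > 0) {
    stop("unknown site_tag(s): ", paste(bad_tag, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atomic coordinates", call. = FALSE)
  }
  if (any(atoms$fragment_id < 0)) stop("fragment_id must be >= 0", call. = FALSE)
  obj <- structure(
    list(
      atoms = atoms,
      label = as.character(label),
      total_charge = as.integer(total_charge),
      n_waters = n_water_fragments(atoms)
    ),
    class = "conformer"
  )
  validate_conformer(obj)
  obj
}

n_water_fragments <- function(atoms) {
  ids <- unique(atoms$fragment_id)
  sum(ids >= 1L)
}

validate_conformer <- function(conf) {
  atoms <- conf$atoms
  wids <- sort(unique(atoms$fragment_id[atoms$fragment_id >= 1L]))
  for (w in wids) {
    frag <- atoms[atoms$fragment_id == w, ]
    comp <- sort(frag$element)
    if (!identical(comp, c("H", "H", "O"))) {
      stop(
        "water fragment ", w, " is not an O,H,H triplet (got ",
        paste(frag$element, collapse = ","), ")",
        call. = FALSE
      )
    }
  }
  if (length(wids) > 0 && !identical(wids, seq_along(wids))) {
    stop("water fragment_ids must be consecutive 1..n", call. = FALSE)
  }
  invisible(conf)
}

#' @export
print.conformer <- function(x, ...) {
  cat(
    "<conformer> ", x$label, ": ", nrow(x$atoms), " atoms, charge ",
    x$total_charge, ", ", x$n_waters, " water(s)\n",
    sep = ""
  )
  invisible(x)
}

#' @export
format.conformer <- function(x, ...) {
  sprintf(
    "<conformer %s: %d atoms, q=%d, %d waters>",
    x$label, nrow(x$atoms), x$total_charge, x$n_waters
  )
}

coords_matrix <- function(conf, idx = NULL) {
  m <- as.matrix(conf$atoms[, c("x", "y", "z")])
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  unname(m)
}

set_coords <- function(conf, m, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(nrow(conf$atoms))
  conf$atoms$x[idx] <- m[, 1]
  conf$atoms$y[idx] <- m[, 2]
  conf$atoms$z[idx] <- m[, 3]
  conf
}

#' Conformer ensemble
#'
#' An ordered collection of conformers sharing the same solute (identical
#' solute atom count and element order), with an associated equilibration
#' temperature.
#'
#' @param conformers List of [conformer()] objects.
#' @param temperature Temperature in kelvin (> 0).
#' @return An object of class `ensemble` (a list of conformers with a
#'   `temperature` attribute).
#' @export
ensemble <- function(conformers, temperature = 298.15) {
  if (length(conformers) == 0) stop("ensemble must be non-empty", call. = FALSE)
  if (!all(vapply(conformers, inherits, logical(1), "conformer"))) {
    stop("all elements must be conformer objects", call. = FALSE)
  }
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  labels <- vapply(conformers, function(c) c$label, character(1))
  if (anyDuplicated(labels)) {
    stop("duplicate conformer labels: ",
      paste(unique(labels[duplicated(labels)]), collapse = ", "),
      call. = FALSE
    )
  }
  solute_sig <- function(c) {
    sol <- c$atoms[c$atoms$fragment_id == 0L, ]
    paste(sol$element, collapse = "")
  }
  sigs <- vapply(conformers, solute_sig, character(1))
  if (length(unique(sigs)) > 1) {
    stop("conformers differ in solute atom count or ordering", call. = FALSE)
  }
  structure(conformers,
    temperature = as.numeric(temperature),
    class = "ensemble"
  )
}

#' @export
print.ensemble <- function(x, ...) {
  cat(
    "<ensemble> ", length(x), " conformer(s) at ",
    attr(x, "temperature"), " K\n",
    sep = ""
  )
  invisible(x)
}

#' @export
`[.ensemble` <- function(x, i) {
  ensemble(unclass(x)[i], temperature = attr(x, "temperature"))
}

ensemble_labels <- function(ens) {
  vapply(ens, function(c) c$label, character(1))
}

#' Flatten an ensemble to a tidy atom table
#'
#' @param x An [ensemble()].
#' @param ... Unused.
#' @return A tibble with one row per atom per frame: `frame`, `label`, plus
#'   the conformer atom columns.
#' @method as_tibble ensemble
#' @export
as_tibble.ensemble <- function(x, ...) {
  purrr::imap_dfr(unclass(x), function(conf, i) {
    dplyr::mutate(conf$atoms,
      frame = as.integer(i), label = conf$label,
      .before = 1
    )
  })
}

#' Rigid water template geometry
#'
#' Returns a 3-atom water (O, H, H) with the gas-phase internal geometry
#' (O-H 0.9572 Angstrom, H-O-H 104.52 degrees), oxygen at the origin and the
#' H-O-H bisector along +z.
#'
#' @param q_o,q_h Partial charges (e) placed on O and each H.
#' @return Tibble of 3 atom rows with `fragment_id = 1`.
#' @export
water_template <- function(q_o = -0.834, q_h = 0.417) {
  half <- WATER_HOH / 2 * pi / 180
  hx <- WATER_OH * sin(half)
  hz <- WATER_OH * cos(half)
  tibble::tibble(
    element = c("O", "H", "H"),
    x = c(0, hx, -hx),
    y = c(0, 0, 0),
    z = c(0, hz, hz),
    fragment_id = 1L,
    site_tag = "OTHER",
    charge = c(q_o, q_h, q_h)
  )
}
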