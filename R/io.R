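# Effective electron counts used as constant form factors.
ELEMENT_ELECTRONS <- c(H = 1, C = 6, N = 7, O = 8, S = 16, P = 15)

#' Atomic model with scattering weights
#'
#' A minimal labeled coordinate set: positions in Å plus an effective
#' electron count per atom used as a constant form factor.
#'
#' @param coords Numeric matrix, n x 3, Å.
#' @param element Character vector of element symbols (H, C, N, O, S, P).
#' @param weight Optional numeric scattering weights (effective electrons);
#'   defaults to the element's electron count.
#' @param id Model name.
#' @return Object of class \code{atomic_model}.
#' @export
atomic_model <- function(coords, element, weight = NULL, id = "model") {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1 || ncol(coords) != 3) stop("coords must be an n x 3 matrix")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  element <- toupper(as.character(element))
  if (length(element) != nrow(coords)) stop("one element per atom required")
  if (is.null(weight)) {
    weight <- unname(ELEMENT_ELECTRONS[element])
    if (any(is.na(weight))) {
      bad <- unique(element[is.na(weight)])
      stop("no scattering weight known for element(s): ", paste(bad, collapse = ", "))
    }
  }
  if (length(weight) != nrow(coords) || any(weight <= 0)) {
    stop("weights must be positive, one per atom")
  }
  structure(list(coords = unname(coords), element = element,
                 weight = as.numeric(weight), id = id),
            class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("atomic model '%s': %d atoms, Rg = %.2f A\n",
              x$id, nrow(x$coords), radius_of_gyration(x)))
  invisible(x)
}

# Infer an element symbol from a PDB atom name (CA -> C, OG1 -> O, ...).
infer_element <- function(atom_name) {
  nm <- gsub("[0-9']", "", trimws(atom_name))
  first <- substr(nm, 1, 1)
  two <- substr(nm, 1, 2)
  ifelse(two %in% names(ELEMENT_ELECTRONS) & !(first %in% names(ELEMENT_ELECTRONS)),
         two, first)
}

#' Read an atomic structure from a PDB file
#'
#' Parses ATOM/HETATM records via \pkg{bio3d}. When the element column is
#' blank the element is inferred from the atom name and a message is logged.
#'
#' @param path Path to a PDB file.
#' @param keep_hydrogens Keep H atoms (default \code{FALSE}; models often
#'   lack them and the form-factor default ignores them).
#' @param id Model name; defaults to the file name.
#' @return An [atomic_model()].
#' @export
read_structure <- function(path, keep_hydrogens = FALSE,
                           id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("PDB parse error in ", path, ": ",
                                           conditionMessage(e)))
  at <- pdb$atom
  elem <- trimws(as.character(at$elesy))
  missing_elem <- is.na(elem) | elem == ""
  if (any(missing_elem)) {
    elem[missing_elem] <- infer_element(at$elety[missing_elem])
    message(sum(missing_elem), " atoms lacked an element field; inferred from atom names")
  }
  elem <- toupper(elem)
  keep <- rep(TRUE, length(elem))
  if (!keep_hydrogens) keep <- elem != "H"
  if (!any(keep)) stop("no atoms left after hydrogen removal")
  atomic_model(cbind(at$x, at$y, at$z)[keep, , drop = FALSE], elem[keep], id = id)
}

#' Write an atomic model to a PDB file
#'
#' @param model An [atomic_model()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(model, path) {
  n <- nrow(model$coords)
  bio3d::write.pdb(file = path, xyz = as.vector(t(model$coords)),
                   elety = model$element, elesy = model$element,
                   resno = seq_len(n), resid = rep("GLY", n),
                   chain = rep("A", n), eleno = seq_len(n))
  invisible(path)
}

#' Write a radial profile as a two-column table
#'
#' Whitespace-separated columns q (Å^-1) and intensity, with '#' comment
#' headers. Round-trips through [read_profile()] to 1e-9 relative.
#'
#' @param profile A \code{radial_profile}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# radial scattering profile",
               "# columns: q [1/Angstrom]  intensity"), con)
  write.table(data.frame(q = profile$q$values, intensity = profile$intensity),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tabular radial profile
#'
#' Accepts whitespace- or comma-separated two-column tables (q, intensity)
#' with optional '#' comment headers.
#'
#' @param path Input path.
#' @return A \code{radial_profile}.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  sep <- if (any(grepl(",", lines))) "," else ""
  tab <- tryCatch(read.table(text = lines, sep = sep, header = FALSE),
                  error = function(e) stop("malformed profile table in ", path,
                                           ": ", conditionMessage(e)))
  if (ncol(tab) < 2) stop("profile table needs two columns (q, intensity)")
  radial_profile(as.numeric(tab[[1]]), as.numeric(tab[[2]]))
}

#' Write a train series as a plain-text bundle
#'
#' Serializes a \code{train_series} into a directory holding JSON metadata
#' (grids, flags, ground truth) and one CSV matrix of per-train x per-pulse
#' profiles.
#'
#' @param series A \code{train_series}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_train_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(q = series$q$values, time_us = series$time_us,
               light_flag = series$light_flag, truth = series$truth)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  flat <- do.call(rbind, lapply(seq_along(series$profiles), function(i) {
    p <- series$profiles[[i]]
    cbind(train = i, pulse = seq_len(ncol(p)), t(p))
  }))
  utils::write.csv(as.data.frame(flat), file.path(dir, "profiles.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a train series written by [write_train_series()]
#'
#' @param dir Bundle directory.
#' @return A \code{train_series}.
#' @export
read_train_series <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  flat <- utils::read.csv(file.path(dir, "profiles.csv"))
  nq <- length(meta$q)
  profiles <- lapply(split(flat, flat$train), function(d) {
    d <- d[order(d$pulse), ]
    t(as.matrix(d[, -(1:2), drop = FALSE]))
  })
  names(profiles) <- NULL
  train_series(profiles = profiles, q = meta$q, time_us = meta$time_us,
               light_flag = meta$light_flag, truth = meta$truth)
}
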