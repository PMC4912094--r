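#' Read a protein structure into a flat atom table
#'
#' Parses a PDB or mmCIF file (dispatched on extension, overridable) via
#' bio3d and returns one row per atom with author chain IDs, residue
#' numbers and insertion codes preserved. Only the first model of
#' multi-model (e.g. NMR) files is used. Alternate locations are resolved
#' by keeping the highest-occupancy conformer; ties keep the first altloc
#' identifier alphabetically.
#'
#' @param path Path to a `.pdb` or `.cif` / `.mmcif` file.
#' @param format `"pdb"`, `"cif"`, or `NULL` to infer from the extension.
#' @return A tibble of class `structure_model` with columns `chain`,
#'   `resno`, `insert`, `auth_res`, `resid`, `atom`, `x`, `y`, `z`,
#'   `occupancy`.
#' @export
read_structure <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") {
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE))
    } else {
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE))
    },
    error = function(e) stop("could not parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("empty model: no ATOM records in ", path, call. = FALSE)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  x <- tibble::tibble(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    insert = as.character(at$insert),
    resid = as.character(at$resid),
    atom = as.character(at$elety),
    alt = as.character(at$alt),
    x = at$x, y = at$y, z = at$z,
    occupancy = at$o
  )
  # altloc: per (chain, residue, atom) keep highest occupancy, ties -> first
  # altloc identifier
  key <- paste(x$chain, x$resno, x$insert, x$atom, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(x)), key), function(i) {
    if (length(i) == 1) return(i)
    o <- x$occupancy[i]
    cand <- i[o == max(o)]
    cand[order(x$alt[cand])][1]
  }), use.names = FALSE)
  x <- x[sort(keep), ]
  x$auth_res <- paste0(x$resno, x$insert)
  x <- x[, c("chain", "resno", "insert", "auth_res", "resid", "atom",
             "x", "y", "z", "occupancy")]
  class(x) <- c("structure_model", class(tibble::tibble()))
  x
}

#' Extract a helix backbone from a structure model
#'
#' Selects the annotated residue range of a chain and assembles a
#' [helix_backbone()]. Residues missing any of N/CA/C/O at the ends of the
#' range are trimmed; a missing backbone atom in the interior is an error,
#' because a hole would silently corrupt segment indexing downstream.
#'
#' @param model A `structure_model` from [read_structure()].
#' @param chain Chain identifier.
#' @param start_res,end_res Author residue numbers bounding the helix
#'   (inclusive).
#' @param helix_id Identifier for the output.
#' @return A [helix_backbone()].
#' @export
extract_helix <- function(model, chain, start_res, end_res,
                          helix_id = paste0(chain, start_res, "-", end_res)) {
  m <- model[model$chain == chain &
               model$resno >= start_res & model$resno <= end_res, ]
  if (nrow(m) == 0) {
    stop("annotated range ", chain, ":", start_res, "-", end_res,
         " not found in model", call. = FALSE)
  }
  res_keys <- unique(paste(m$resno, m$insert, sep = "\r"))
  complete <- vapply(res_keys, function(k) {
    a <- m$atom[paste(m$resno, m$insert, sep = "\r") == k]
    all(c("N", "CA", "C", "O") %in% a)
  }, logical(1))
  # trim incomplete residues at either end of the range
  first <- which(complete)[1]
  last <- rev(which(complete))[1]
  if (is.na(first)) {
    stop("no residue in ", chain, ":", start_res, "-", end_res,
         " has a complete N/CA/C/O backbone", call. = FALSE)
  }
  inner <- first:last
  if (!all(complete[inner])) {
    bad <- res_keys[inner][!complete[inner]]
    stop("interior residue(s) ", paste(gsub("\r", "", bad), collapse = ", "),
         " missing backbone atoms in ", chain, ":", start_res, "-", end_res,
         call. = FALSE)
  }
  kept <- res_keys[inner]
  m <- m[paste(m$resno, m$insert, sep = "\r") %in% kept &
           m$atom %in% c("N", "CA", "C", "O"), ]
  ord <- match(paste(m$resno, m$insert, sep = "\r"), kept)
  helix_backbone(tibble::tibble(
    helix_id = helix_id,
    chain_id = chain,
    res_index = ord - 1L,
    auth_res = m$auth_res,
    resid = m$resid,
    atom = m$atom,
    x = m$x, y = m$y, z = m$z
  ))
}

#' Merge helix annotations separated by one or two residues
#'
#' Helical segments on the same chain separated by a gap of at most two
#' residues are combined into one spanning annotation; merging is applied
#' iteratively until no further pair qualifies. The merged segment keeps
#' the first segment's `helix_id`.
#'
#' @param annotations Tibble with columns `helix_id`, `chain`, `start_res`,
#'   `end_res` (author numbering, `start_res <= end_res`).
#' @return Tibble of merged annotations, sorted by chain and start.
#' @export
#' @examples
#' a <- tibble::tibble(helix_id = c("h1", "h2"), chain = "A",
#'                     start_res = c(5L, 17L), end_res = c(15L, 25L))
#' merge_annotations(a)  # gap of 1 -> single 5-25 annotation
merge_annotations <- function(annotations) {
  if (nrow(annotations) == 0) return(annotations)
  out <- lapply(split(annotations, annotations$chain), function(a) {
    a <- a[order(a$start_res), ]
    merged <- a[1, ]
    for (i in seq_len(nrow(a))[-1]) {
      gap <- a$start_res[i] - merged$end_res[nrow(merged)] - 1L
      if (gap <= 2L) {
        merged$end_res[nrow(merged)] <-
          max(merged$end_res[nrow(merged)], a$end_res[i])
      } else {
        merged <- rbind(merged, a[i, ])
      }
    }
    merged
  })
  out <- dplyr::bind_rows(out)
  tibble::as_tibble(out[order(out$chain, out$start_res), ])
}

#' Read a helix annotation table
#'
#' Tab-separated sidecar file with columns `helix_id`, `chain`,
#' `start_res`, `end_res` (author residue numbers). Lines starting with
#' `#` are comments.
#'
#' @param path Path to the TSV.
#' @return A tibble of annotations.
#' @export
read_helix_annotations <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  needed <- c("helix_id", "chain", "start_res", "end_res")
  if (!all(needed %in% names(x))) {
    stop("annotation table needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(x)
}

#' Extract all annotated helices from a structure
#'
#' @param model A `structure_model`.
#' @param annotations Annotation tibble (see [read_helix_annotations()]).
#' @return Named list of [helix_backbone()] objects keyed by `helix_id`.
#' @export
extract_helices <- function(model, annotations) {
  out <- lapply(seq_len(nrow(annotations)), function(i) {
    extract_helix(model, annotations$chain[i], annotations$start_res[i],
                  annotations$end_res[i], helix_id = annotations$helix_id[i])
  })
  names(out) <- annotations$helix_id
  out
}

#' Write a helix backbone as a PDB file
#'
#' @param helix A [helix_backbone()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_helix_pdb <- function(helix, path) {
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(as.matrix(helix[, c("x", "y", "z")]))),
    resno = as.integer(helix$auth_res),
    resid = helix$resid,
    eleno = seq_len(nrow(helix)),
    elety = helix$atom,
    chain = helix$chain_id,
    o = rep(1, nrow(helix)),
    b = rep(0, nrow(helix))
  )
  invisible(path)
}

#' Write a helix backbone as a minimal mmCIF file
#'
#' Emits a bare `atom_site` loop (the subset of mmCIF needed to round-trip
#' the fixture coordinates); this is a minimal writer for synthetic
#' fixtures, not a general-purpose mmCIF exporter.
#'
#' @param helix A [helix_backbone()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_helix_cif <- function(helix, path) {
  hdr <- c(
    paste0("data_", gsub("[^A-Za-z0-9]", "_", helix$helix_id[1])),
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"
  )
  elem <- substr(helix$atom, 1, 1)
  body <- sprintf(
    "ATOM %d %s %s . %s %s 1 %s ? %.3f %.3f %.3f 1.00 0.00 ? %s %s %s %s 1",
    seq_len(nrow(helix)), elem, helix$atom, helix$resid, helix$chain_id,
    helix$auth_res,
    helix$x, helix$y, helix$z,
    helix$auth_res, helix$resid, helix$chain_id, helix$atom
  )
  writeLines(c(hdr, body, "#"), path)
  invisible(path)
}

#' Write an angle profile as TSV with a unit-bearing header
#'
#' @param profile An `angle_profile` tibble from [measure_angles()].
#' @param path Output path.
#' @param extra_comments Optional character vector of extra `#` header lines.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path, extra_comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("# helixkink angle profile",
           "# theta_deg, epsilon_deg in degrees; r_n, r_c in Angstrom")
  if (length(extra_comments) > 0) hdr <- c(hdr, paste0("# ", extra_comments))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(profile), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an angle profile written by [write_profile_tsv()]
#' @param path Path to the TSV.
#' @return An `angle_profile` tibble.
#' @export
read_profile_tsv <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  x$auth_res <- as.character(x$auth_res)
  x <- tibble::as_tibble(x)
  class(x) <- c("angle_profile", class(tibble::tibble()))
  x
}
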