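#' Ordered C-alpha chain
#'
#' Container for the single-bead-per-residue representation used throughout
#' the package: one C-alpha coordinate per residue of one chain, with author
#' residue numbering preserved so that ranges such as 196--210 select the
#' same residues as in the deposited structure.
#'
#' @param residue_ids integer vector of author residue numbers, strictly
#'   increasing.
#' @param coords numeric matrix, one row per residue, columns x/y/z in
#'   Angstrom.
#' @param residue_names character vector of 3-letter residue codes (recycled
#'   if length 1).
#' @param chain_id single chain identifier character.
#' @param label free-text label carried through truncation and topology
#'   building.
#' @return An object of class `calpha_structure`.
#' @export
calpha_structure <- function(residue_ids, coords, residue_names = "ALA",
                             chain_id = "A", label = "") {
  residue_ids <- as.integer(residue_ids)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  n <- length(residue_ids)
  if (n < 2L) stop("a calpha_structure needs at least 2 residues")
  if (ncol(coords) != 3L || nrow(coords) != n)
    stop("'coords' must be an n x 3 matrix matching 'residue_ids'")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  if (any(diff(residue_ids) <= 0L))
    stop("'residue_ids' must be strictly increasing")
  residue_names <- rep_len(as.character(residue_names), n)
  structure(
    list(residue_ids = residue_ids, residue_names = residue_names,
         coords = coords, chain_id = as.character(chain_id)[1L],
         label = as.character(label)[1L]),
    class = "calpha_structure")
}

#' @export
print.calpha_structure <- function(x, ...) {
  cat(sprintf("calpha_structure '%s': %d residues (%d-%d), chain %s\n",
              x$label, length(x$residue_ids), min(x$residue_ids),
              max(x$residue_ids), x$chain_id))
  invisible(x)
}

#' Read C-alpha coordinates from PDB text or file
#'
#' Extracts one CA atom per residue for a single chain and model. Alternate
#' locations other than blank or 'A' are dropped; a residue left with more
#' than one CA record is an error, as are insertion codes (the frataxin
#' starting structure has neither, and silent disambiguation hides real
#' bookkeeping problems). HETATM records are ignored.
#'
#' @param pdb either a path to a PDB file or a character vector of PDB-format
#'   lines.
#' @param chain chain identifier to extract; if `NULL` the file must contain
#'   exactly one chain.
#' @param model_index 1-based model number for multi-model files.
#' @param label optional label for the returned structure; defaults to the
#'   chain id.
#' @return A [calpha_structure()].
#' @export
read_pdb_calpha <- function(pdb, chain = NULL, model_index = 1L,
                            label = NULL) {
  path <- pdb
  if (length(pdb) > 1L || grepl("\n", pdb[1L], fixed = TRUE) ||
      grepl("^(ATOM|HETATM|MODEL|HEADER|REMARK|CRYST)", pdb[1L])) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(pdb, "\n", fixed = TRUE)), path)
  }
  pdbobj <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- pdbobj$atom
  atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no ATOM records in PDB input")
  chains <- sort(unique(atoms$chain))
  if (is.null(chain)) {
    if (length(chains) != 1L)
      stop("PDB input has chains [", paste(chains, collapse = ", "),
           "]; specify 'chain'")
    chain <- chains
  }
  if (!chain %in% chains)
    stop("chain '", chain, "' not found; available chains: ",
         paste(chains, collapse = ", "))
  sel <- atoms$chain == chain & atoms$elety == "CA"
  atoms_idx <- which(sel)
  ca <- atoms[sel, , drop = FALSE]
  if (nrow(ca) == 0L) stop("no CA atom records for chain '", chain, "'")
  if (any(!is.na(ca$insert) & ca$insert != ""))
    stop("insertion codes are not supported; renumber the input")
  keep <- is.na(ca$alt) | ca$alt %in% c("", "A")
  ca <- ca[keep, , drop = FALSE]
  atoms_idx <- atoms_idx[keep]
  if (nrow(ca) == 0L) stop("no CA records with altloc blank or 'A'")
  if (anyDuplicated(ca$resno))
    stop("duplicate CA records for residue(s) ",
         paste(unique(ca$resno[duplicated(ca$resno)]), collapse = ", "),
         " after altloc filtering")
  nmod <- if (is.matrix(pdbobj$xyz)) nrow(pdbobj$xyz) else 1L
  if (model_index < 1L || model_index > nmod)
    stop("model_index ", model_index, " out of range (file has ", nmod,
         " model", if (nmod > 1L) "s", ")")
  xyz <- if (is.matrix(pdbobj$xyz)) pdbobj$xyz[model_index, ] else
    as.numeric(pdbobj$xyz)
  coords <- matrix(xyz, ncol = 3L, byrow = TRUE)[atoms_idx, , drop = FALSE]
  ord <- order(ca$resno)
  calpha_structure(residue_ids = ca$resno[ord],
                   coords = coords[ord, , drop = FALSE],
                   residue_names = ca$resid[ord], chain_id = chain,
                   label = if (is.null(label)) paste0("chain", chain) else label)
}

#' Truncate a structure to a contiguous residue range
#'
#' In-silico deletion of terminal segments, e.g. removing the frataxin
#' C-terminal region by keeping residues 90--195 of the 90--210 construct.
#' Residue numbering is preserved; the label is annotated with the range.
#'
#' @param structure a [calpha_structure()].
#' @param keep_first,keep_last author residue ids delimiting the kept range
#'   (inclusive); both must be present in the structure.
#' @return A [calpha_structure()] restricted to the range.
#' @export
truncate_structure <- function(structure, keep_first, keep_last) {
  stopifnot(inherits(structure, "calpha_structure"))
  if (keep_first > keep_last) stop("'keep_first' must be <= 'keep_last'")
  ids <- structure$residue_ids
  if (!keep_first %in% ids || !keep_last %in% ids)
    stop("residue id(s) ",
         paste(setdiff(c(keep_first, keep_last), ids), collapse = ", "),
         " not present in the structure")
  sel <- ids >= keep_first & ids <= keep_last
  calpha_structure(residue_ids = ids[sel],
                   coords = structure$coords[sel, , drop = FALSE],
                   residue_names = structure$residue_names[sel],
                   chain_id = structure$chain_id,
                   label = sprintf("%s[%d-%d]", structure$label,
                                   as.integer(keep_first),
                                   as.integer(keep_last)))
}

#' Build a C-alpha structure-based (Go-type) topology
#'
#' Derives the native reference geometry (bond lengths, bond angles, signed
#' dihedrals) and the native contact map from the input coordinates. A native
#' contact is a residue pair with sequence separation j >= i+4 whose
#' C-alpha--C-alpha distance lies in `contact_range` (default 4.0--6.0
#' Angstrom); closer pairs in sequence are already restrained by the bonded
#' terms. All native contacts are equally weighted in the 10--12 attractive
#' well; remaining pairs with j >= i+4 repel through a smooth excluded-volume
#' wall, `epsilon * ((sigma_ij/r)^6 - 1)^2` for `r < sigma_ij` and zero in
#' both value and force beyond, whose per-pair radius `sigma_ij` is the
#' smaller of `sigma_nonnative` and the pair's native distance. The native
#' conformation is therefore exactly the energy minimum, with bonded and
#' non-native terms both zero there.
#'
#' Dihedrals whose defining triple of bonds is collinear in the native
#' structure have no defined reference angle; these are disabled (zero force
#' constant) with a warning. Force constants default to K_r = 100, K_theta =
#' 20, K_phi1 = 1, K_phi3 = 0.5 in units of the contact energy epsilon.
#'
#' @param structure a [calpha_structure()].
#' @param epsilon contact well depth; the reduced energy unit (default 1).
#' @param K_r,K_theta,K_phi1,K_phi3 force constants in multiples of epsilon.
#' @param contact_range length-2 numeric, native-contact distance window in
#'   Angstrom.
#' @param min_seq_sep minimum sequence separation (j - i) for contact and
#'   repulsive pairs; default 4.
#' @param sigma_nonnative excluded-volume radius for non-native pairs,
#'   Angstrom.
#' @param bond_range sanity gate on consecutive C-alpha distances, Angstrom;
#'   violations (chain breaks) are an error.
#' @return An object of class `go_topology`.
#' @export
build_topology <- function(structure, epsilon = 1, K_r = 100 * epsilon,
                           K_theta = 20 * epsilon, K_phi1 = epsilon,
                           K_phi3 = 0.5 * epsilon,
                           contact_range = c(4.0, 6.0), min_seq_sep = 4L,
                           sigma_nonnative = 4.0, bond_range = c(2.0, 4.5)) {
  stopifnot(inherits(structure, "calpha_structure"))
  x <- structure$coords
  n <- nrow(x)
  if (n < 4L) stop("need at least 4 residues to define a dihedral")

  bond_r0 <- sqrt(rowSums((x[-1L, , drop = FALSE] -
                           x[-n, , drop = FALSE])^2))
  if (any(bond_r0 <= bond_range[1L] | bond_r0 >= bond_range[2L]))
    stop("consecutive C-alpha distance outside (", bond_range[1L], ", ",
         bond_range[2L], ") Angstrom at position(s) ",
         paste(which(bond_r0 <= bond_range[1L] | bond_r0 >= bond_range[2L]),
               collapse = ", "),
         "; chain break or non-protein geometry")

  theta0 <- vapply(seq_len(n - 2L), function(a) {
    u <- x[a, ] - x[a + 1L, ]; v <- x[a + 2L, ] - x[a + 1L, ]
    acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
  }, numeric(1L))

  dih <- lapply(seq_len(n - 3L), function(d) {
    b1 <- x[d + 1L, ] - x[d, ]
    b2 <- x[d + 2L, ] - x[d + 1L, ]
    b3 <- x[d + 3L, ] - x[d + 2L, ]
    n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
    degenerate <- sqrt(sum(n1^2)) < 1e-8 * sum(abs(b1) + abs(b2)) ||
      sqrt(sum(n2^2)) < 1e-8 * sum(abs(b2) + abs(b3))
    phi <- if (degenerate) 0 else
      atan2(sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
    list(phi0 = phi, enabled = !degenerate)
  })
  phi0 <- vapply(dih, `[[`, numeric(1L), "phi0")
  dih_enabled <- vapply(dih, `[[`, logical(1L), "enabled")
  if (any(!dih_enabled))
    warning(sum(!dih_enabled), " dihedral(s) with collinear native geometry ",
            "disabled (no defined reference angle)")

  dmat <- as.matrix(stats::dist(x))
  pairs <- which(upper.tri(dmat), arr.ind = TRUE)
  pairs <- pairs[pairs[, 2L] - pairs[, 1L] >= min_seq_sep, , drop = FALSE]
  d <- dmat[pairs]
  is_native <- d >= contact_range[1L] & d <= contact_range[2L]
  contacts <- data.frame(i = pairs[is_native, 1L], j = pairs[is_native, 2L],
                         r0 = d[is_native])
  contacts <- contacts[order(contacts$i, contacts$j), , drop = FALSE]
  rownames(contacts) <- NULL
  nonnative <- data.frame(i = pairs[!is_native, 1L], j = pairs[!is_native, 2L],
                          sigma = pmin(sigma_nonnative, d[!is_native]))
  nonnative <- nonnative[order(nonnative$i, nonnative$j), , drop = FALSE]
  rownames(nonnative) <- NULL

  structure(
    list(n_residues = n, residue_ids = structure$residue_ids,
         label = structure$label, coords = x,
         bonds = data.frame(i = seq_len(n - 1L), r0 = bond_r0),
         angles = data.frame(i = seq_len(n - 2L), theta0 = theta0),
         dihedrals = data.frame(i = seq_len(n - 3L), phi0 = phi0,
                                enabled = dih_enabled),
         contacts = contacts, nonnative = nonnative,
         epsilon = epsilon, K_r = K_r, K_theta = K_theta,
         K_phi1 = K_phi1, K_phi3 = K_phi3,
         sigma_nonnative = sigma_nonnative,
         contact_range = contact_range, min_seq_sep = as.integer(min_seq_sep)),
    class = "go_topology")
}

#' @export
print.go_topology <- function(x, ...) {
  cat(sprintf(paste0("go_topology '%s': %d residues, %d bonds, %d angles, ",
                     "%d dihedrals (%d active), %d native contacts\n"),
              x$label, x$n_residues, nrow(x$bonds), nrow(x$angles),
              nrow(x$dihedrals), sum(x$dihedrals$enabled), nrow(x$contacts)))
  invisible(x)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Serialize a topology to a plain-text table set
#'
#' Writes constants, reference coordinates and the bonded/contact tables as
#' TSV blocks separated by `[section]` headers; [read_topology()] restores an
#' equivalent topology (non-native pairs are rebuilt from the coordinates).
#'
#' @param topology a `go_topology`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_topology <- function(topology, file) {
  stopifnot(inherits(topology, "go_topology"))
  con <- file(file, "w")
  on.exit(close(con))
  wr <- function(...) cat(..., "\n", sep = "", file = con)
  wr("[constants]")
  for (k in c("epsilon", "K_r", "K_theta", "K_phi1", "K_phi3",
              "sigma_nonnative", "min_seq_sep"))
    wr(k, "\t", format(topology[[k]], digits = 17))
  wr("contact_lo\t", format(topology$contact_range[1L], digits = 17))
  wr("contact_hi\t", format(topology$contact_range[2L], digits = 17))
  wr("label\t", topology$label)
  wtab <- function(name, df) {
    wr("[", name, "]")
    wr(paste(names(df), collapse = "\t"))
    for (r in seq_len(nrow(df)))
      wr(paste(vapply(df[r, ], function(v)
        if (is.numeric(v)) format(v, digits = 17) else as.character(v),
        character(1L)), collapse = "\t"))
  }
  coords <- data.frame(resid = topology$residue_ids,
                       x = topology$coords[, 1L], y = topology$coords[, 2L],
                       z = topology$coords[, 3L])
  wtab("coords", coords)
  wtab("bonds", topology$bonds)
  wtab("angles", topology$angles)
  wtab("dihedrals", topology$dihedrals)
  wtab("contacts", topology$contacts)
  invisible(file)
}

#' Read a topology written by [write_topology()]
#'
#' @param file path to a topology text file.
#' @return A `go_topology`.
#' @export
read_topology <- function(file) {
  lines <- readLines(file)
  heads <- grep("^\\[", lines)
  sections <- sub("^\\[(.*)\\]$", "\\1", lines[heads])
  bounds <- c(heads, length(lines) + 1L)
  blocks <- stats::setNames(lapply(seq_along(heads), function(k)
    lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]), sections)
  const_kv <- do.call(rbind, strsplit(blocks$constants, "\t", fixed = TRUE))
  const <- stats::setNames(as.list(const_kv[, 2L]), const_kv[, 1L])
  rtab <- function(b) {
    utils::read.table(text = paste(b, collapse = "\n"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
  }
  coords <- rtab(blocks$coords)
  st <- calpha_structure(coords$resid,
                         as.matrix(coords[, c("x", "y", "z")]),
                         label = const$label)
  build_topology(st, epsilon = as.numeric(const$epsilon),
                 K_r = as.numeric(const$K_r),
                 K_theta = as.numeric(const$K_theta),
                 K_phi1 = as.numeric(const$K_phi1),
                 K_phi3 = as.numeric(const$K_phi3),
                 contact_range = c(as.numeric(const$contact_lo),
                                   as.numeric(const$contact_hi)),
                 min_seq_sep = as.integer(const$min_seq_sep),
                 sigma_nonnative = as.numeric(const$sigma_nonnative))
}
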