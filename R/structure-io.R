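AA_321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA_123 <- stats::setNames(names(AA_321), AA_321)

#' Coerce a protein sequence to a one-letter residue vector
#'
#' @param sequence a single string or a character vector of one-letter
#'   residue codes.
#' @return character vector, one residue per element.
#' @export
as_residue_vector <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  sequence <- toupper(as.character(sequence))
  bad <- !sequence %in% AA_321
  if (any(bad))
    stop("unknown residue code(s): ", paste(unique(sequence[bad]), collapse = ", "))
  sequence
}

#' A predicted protein structure model (Calpha trace)
#'
#' Per-residue Calpha coordinates, one-letter sequence and per-residue
#' confidence (pLDDT, 0-100), with 1-based contiguous residue numbering.
#'
#' @param xyz n x 3 numeric matrix of Calpha coordinates in Angstrom.
#' @param sequence one-letter residue codes (string or vector), length n.
#' @param plddt per-residue confidence in [0, 100], length n.
#' @param model_id identifier string.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(xyz, sequence, plddt, model_id = "model") {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  sequence <- as_residue_vector(sequence)
  n <- nrow(xyz)
  if (ncol(xyz) != 3 || any(!is.finite(xyz)))
    stop("'xyz' must be a finite n x 3 matrix")
  if (length(sequence) != n) stop("sequence length != number of residues")
  if (length(plddt) != n || any(plddt < 0 | plddt > 100))
    stop("'plddt' must give one value in [0, 100] per residue")
  structure(list(resno = seq_len(n), sequence = sequence, xyz = xyz,
                 plddt = as.numeric(plddt), model_id = model_id),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model '%s': %d residues, mean pLDDT %.1f\n",
              x$model_id, length(x$resno), mean(x$plddt)))
  invisible(x)
}

#' Read a Calpha structure model from a PDB file
#'
#' Parses ATOM records of a Calpha-only PDB in the structure-predictor
#' convention: per-residue confidence (pLDDT) stored in the B-factor
#' column. Residues must be contiguously numbered unless
#' `allow_breaks = TRUE`, in which case numbering is compacted.
#'
#' @param path PDB file path.
#' @param allow_breaks tolerate gaps in residue numbering.
#' @return a [structure_model()].
#' @export
read_structure <- function(path, allow_breaks = FALSE) {
  lines <- readLines(path)
  atom <- lines[startsWith(lines, "ATOM")]
  name <- trimws(substr(atom, 13, 16))
  ca <- atom[name == "CA"]
  if (length(ca) == 0) stop("no Calpha (CA) atoms in ", path)
  resname <- trimws(substr(ca, 18, 20))
  if (any(!resname %in% names(AA_321)))
    stop("non-standard residue name(s): ",
         paste(unique(resname[!resname %in% names(AA_321)]), collapse = ", "))
  resno <- as.integer(substr(ca, 23, 26))
  xyz <- cbind(as.numeric(substr(ca, 31, 38)),
               as.numeric(substr(ca, 39, 46)),
               as.numeric(substr(ca, 47, 54)))
  bfac <- suppressWarnings(as.numeric(substr(ca, 61, 66)))
  if (anyNA(bfac)) stop("non-numeric B-factor (pLDDT) column in ", path)
  if (anyNA(xyz)) stop("non-numeric coordinates in ", path)
  o <- order(resno)
  resno <- resno[o]
  if (any(diff(resno) != 1L) && !allow_breaks)
    stop("chain break in residue numbering (use allow_breaks = TRUE to compact)")
  structure_model(xyz = xyz[o, , drop = FALSE],
                  sequence = unname(AA_321[resname[o]]),
                  plddt = bfac[o],
                  model_id = sub("\\.pdb$", "", basename(path)))
}

#' Write a Calpha structure model as PDB
#'
#' Emits one ATOM record per residue (Calpha only) with the pLDDT score
#' in the B-factor column, coordinates at the format's 3-decimal
#' precision.
#'
#' @param model a [structure_model()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  recs <- sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    model$resno, AA_123[model$sequence], model$resno,
    model$xyz[, 1], model$xyz[, 2], model$xyz[, 3],
    1.00, model$plddt)
  writeLines(c(recs, "END"), path)
  invisible(path)
}

#' Write / read protein sequences as FASTA
#'
#' @param sequences named list (or character vector) of sequences; each a
#'   string or one-letter residue vector.
#' @param path file path.
#' @return `read_fasta` returns a named list of one-letter residue
#'   vectors.
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences))) names(sequences) <- paste0("seq", seq_along(sequences))
  out <- unlist(lapply(names(sequences), function(nm) {
    s <- paste(as_residue_vector(sequences[[nm]]), collapse = "")
    c(paste0(">", nm), substring(s, seq(1, nchar(s), 60),
                                 pmin(seq(1, nchar(s), 60) + 59, nchar(s))))
  }))
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("no FASTA headers in ", path)
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- lapply(seq_along(hdr), function(i)
    as_residue_vector(paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")))
  names(seqs) <- sub("^>\\s*(\\S+).*", "\\1", lines[hdr])
  seqs
}
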