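#' @title Molecule file I/O: XYZ and SDF (MOL V2000)
#' @name molecule_io
#' @description
#' Multi-record XYZ (count line, comment line, `El x y z` per atom) and
#' SDF/MOL V2000 read and write. Bond blocks in SDF are ignored on read:
#' bonds are inferred downstream from atom types and inter-atomic distances.
#' Formal charges round-trip through `M  CHG` lines.
NULL

#' Read molecules from an XYZ or SDF file
#'
#' @param path file path.
#' @param format "xyz" or "sdf"; guessed from the extension when NULL.
#' @param vocab element vocabulary used to screen atom types.
#' @param permissive if TRUE, molecules containing out-of-vocabulary elements
#'   are skipped with a warning instead of raising an error.
#' @return list of `molecule` objects (possibly empty).
#' @export
read_molecules <- function(path, format = NULL, vocab = QM9_VOCAB,
                           permissive = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  format <- format %||% guess_format(path)
  lines <- readLines(path, warn = FALSE)
  mols <- switch(format,
                 xyz = parse_xyz(lines, path),
                 sdf = parse_sdf(lines, path),
                 stop("unknown format: ", format))
  screen_vocab(mols, vocab, permissive)
}

#' Write molecules to an XYZ or SDF file
#'
#' Round-trip contract: `read_molecules(write_molecules(m))` reproduces
#' coordinates to 1e-4 Angstrom (the V2000/XYZ print precision) and types and
#' charges exactly.
#'
#' @param mols list of `molecule` objects (may be empty).
#' @param path output path.
#' @param format "xyz" or "sdf"; guessed from the extension when NULL.
#' @export
write_molecules <- function(mols, path, format = NULL) {
  format <- format %||% guess_format(path)
  lines <- switch(format,
                  xyz = unlist(lapply(mols, format_xyz)),
                  sdf = unlist(lapply(mols, format_sdf)),
                  stop("unknown format: ", format))
  writeLines(if (is.null(lines)) character(0) else lines, path)
  invisible(path)
}

#' Compact dataset container
#'
#' Single-file container for large processed datasets (e.g. the packaged
#' QM9/GEOM-Drugs arrays): flat coordinate/type/charge arrays plus the size
#' vector, written as a versioned RDS. Round-trips exactly.
#'
#' @param mols list of `molecule` objects.
#' @param path output file (conventionally `.rds`).
#' @export
write_dataset_container <- function(mols, path) {
  sizes <- vapply(mols, n_atoms, integer(1))
  obj <- list(version = 1L,
              sizes = sizes,
              coords = do.call(rbind, lapply(mols, `[[`, "coords")),
              types = unlist(lapply(mols, `[[`, "types")),
              charges = unlist(lapply(mols, `[[`, "charges")))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_dataset_container
#' @return `read_dataset_container`: list of `molecule` objects.
#' @export
read_dataset_container <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, 1L))
    stop("unsupported dataset container version")
  ends <- cumsum(obj$sizes)
  starts <- ends - obj$sizes + 1L
  lapply(seq_along(obj$sizes), function(i) {
    idx <- starts[i]:ends[i]
    molecule(obj$coords[idx, , drop = FALSE], obj$types[idx],
             obj$charges[idx])
  })
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xyz")) return("xyz")
  if (ext %in% c("sdf", "mol")) return("sdf")
  stop("cannot guess format from extension: ", path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

screen_vocab <- function(mols, vocab, permissive) {
  ok <- vapply(mols, function(m) all(m$types %in% vocab), logical(1))
  if (all(ok)) return(mols)
  if (!permissive) {
    bad <- setdiff(unique(unlist(lapply(mols, `[[`, "types"))), vocab)
    stop("element(s) outside vocabulary: ", paste(bad, collapse = ", "))
  }
  warning(sum(!ok), " molecule(s) skipped: out-of-vocabulary elements")
  mols[ok]
}

parse_xyz <- function(lines, path) {
  mols <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop(sprintf("%s: line %d: expected an atom count", path, i))
    if (i + 1L + n > length(lines))
      stop(sprintf("%s: record starting at line %d is truncated", path, i))
    comment <- lines[i + 1L]
    block <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(toks, length, integer(1)) < 4L)
    if (length(bad))
      stop(sprintf("%s: line %d: malformed atom line", path, i + 1L + bad[1]))
    types <- vapply(toks, `[[`, character(1), 1L)
    xyz <- t(vapply(toks, function(tk)
      suppressWarnings(as.numeric(tk[2:4])), numeric(3)))
    if (any(!is.finite(xyz)))
      stop(sprintf("%s: non-numeric coordinate in record at line %d", path, i))
    props <- parse_xyz_comment(comment)
    mols[[length(mols) + 1L]] <- molecule(xyz, types, props = props)
    i <- i + 2L + n
  }
  mols
}

# comment lines of the form "key=value key=value" carry property labels
parse_xyz_comment <- function(comment) {
  toks <- regmatches(comment,
                     gregexpr("[A-Za-z_][A-Za-z0-9_]*=-?[0-9.eE+-]+", comment))[[1]]
  if (!length(toks)) return(NULL)
  kv <- strsplit(toks, "=", fixed = TRUE)
  vals <- suppressWarnings(as.numeric(vapply(kv, `[[`, character(1), 2L)))
  keep <- is.finite(vals)
  if (!any(keep)) return(NULL)
  stats::setNames(as.list(vals[keep]),
                  vapply(kv, `[[`, character(1), 1L)[keep])
}

format_xyz <- function(mol) {
  props <- mol$props
  comment <- if (length(props))
    paste(sprintf("%s=%.10g", names(props), as.numeric(props)), collapse = " ")
  else ""
  c(as.character(n_atoms(mol)), comment,
    sprintf("%-3s %12.6f %12.6f %12.6f",
            mol$types, mol$coords[, 1], mol$coords[, 2], mol$coords[, 3]))
}

parse_sdf <- function(lines, path) {
  # split on $$$$ record terminators
  ends <- grep("^\\$\\$\\$\\$\\s*$", lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  if (!length(ends)) {
    if (!any(nzchar(trimws(lines)))) return(list())
    starts <- 1L; ends <- length(lines) + 1L  # single record, no terminator
  }
  mols <- list()
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:(ends[r] - 1L)]
    block <- block[cumsum(nzchar(trimws(block))) > 0 | nzchar(trimws(block))]
    if (!any(nzchar(trimws(block)))) next
    mols[[length(mols) + 1L]] <- parse_molfile(block, path, starts[r])
  }
  mols
}

parse_molfile <- function(block, path, at_line) {
  if (length(block) < 4L)
    stop(sprintf("%s: molfile record at line %d is truncated", path, at_line))
  counts <- block[4L]
  natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(natoms) || natoms < 1L)
    stop(sprintf("%s: bad counts line in record at line %d", path, at_line))
  if (length(block) < 4L + natoms)
    stop(sprintf("%s: atom block truncated in record at line %d", path, at_line))
  atom_lines <- block[5:(4L + natoms)]
  toks <- strsplit(trimws(atom_lines), "\\s+")
  xyz <- t(vapply(toks, function(tk) suppressWarnings(as.numeric(tk[1:3])),
                  numeric(3)))
  types <- vapply(toks, `[[`, character(1), 4L)
  if (any(!is.finite(xyz)))
    stop(sprintf("%s: malformed atom line in record at line %d", path, at_line))
  charges <- integer(natoms)
  for (ln in grep("^M  CHG", block, value = TRUE)) {
    tk <- strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]]
    npairs <- as.integer(tk[1])
    for (p in seq_len(npairs)) {
      idx <- as.integer(tk[2L * p])
      charges[idx] <- as.integer(tk[2L * p + 1L])
    }
  }
  molecule(xyz, types, charges)
}

format_sdf <- function(mol) {
  n <- n_atoms(mol)
  header <- c("gcdiff molecule", "  gcdiff", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, 0L)
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   mol$coords[, 1], mol$coords[, 2], mol$coords[, 3], mol$types)
  chg <- which(mol$charges != 0L)
  chg_lines <- if (length(chg)) {
    # M CHG lines carry at most 8 atom/charge pairs each
    grp <- split(chg, ceiling(seq_along(chg) / 8))
    vapply(grp, function(g) {
      paste0(sprintf("M  CHG%3d", length(g)),
             paste0(sprintf("%4d%4d", g, mol$charges[g]), collapse = ""))
    }, character(1))
  } else character(0)
  c(header, counts, atoms, chg_lines, "M  END", "$$$$")
}
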