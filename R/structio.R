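#' Coordinate container for protein models
#'
#' A `structure3d` holds an ordered atom table plus a title. It is the
#' universal coordinate container of the package: readers produce it,
#' generators emit it, and all geometric operations consume it. Residues are
#' addressed by `(chain_id, res_num)` using the numbering of the source file
#' (author numbering), never a sequential index.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `res_name`, `chain_id`, `res_num`, `x`, `y`, `z` (coordinates in
#'   Angstrom).
#' @param title character title.
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(atoms, title = "") {
  required <- c("serial", "name", "element", "res_name", "chain_id",
                "res_num", "x", "y", "z")
  if (!is.data.frame(atoms) || !all(required %in% names(atoms)))
    stop("atoms must be a data.frame with columns: ",
         paste(required, collapse = ", "))
  if (nrow(atoms) == 0L)
    stop("structure3d must contain at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("all coordinates must be finite")
  key <- paste(atoms$chain_id, atoms$res_num, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate (chain_id, res_num, name) atom addresses: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  atoms <- atoms[required]
  atoms$res_num <- as.integer(atoms$res_num)
  atoms$serial <- as.integer(atoms$serial)
  rownames(atoms) <- NULL
  out <- list(atoms = atoms, title = as.character(title)[1])
  class(out) <- "structure3d"
  out
}

#' @export
print.structure3d <- function(x, ...) {
  ch <- unique(x$atoms$chain_id)
  cat(sprintf("structure3d: %d atoms, %d residues, chains {%s}%s\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain_id, x$atoms$res_num))),
              paste(ch, collapse = ","),
              if (nzchar(x$title)) paste0(" - ", x$title) else ""))
  invisible(x)
}

#' Number of atoms in a structure
#' @param x structure3d
#' @return integer atom count
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' Extract C-alpha coordinates as a matrix
#'
#' Returns the coordinates of `CA` atoms (chain order as stored), with
#' rownames `"<chain>:<res_num>"` so rows can be addressed by residue.
#'
#' @param x structure3d
#' @param chain optional chain id filter
#' @return numeric matrix with columns x, y, z
#' @export
ca_coords <- function(x, chain = NULL) {
  a <- x$atoms[x$atoms$name == "CA", , drop = FALSE]
  if (!is.null(chain)) a <- a[a$chain_id %in% chain, , drop = FALSE]
  m <- as.matrix(a[c("x", "y", "z")])
  rownames(m) <- paste0(a$chain_id, ":", a$res_num)
  m
}

#' Look up the C-alpha position of one residue
#' @param x structure3d
#' @param chain chain id
#' @param res_num residue number (author numbering)
#' @return length-3 numeric vector
#' @export
ca_site <- function(x, chain, res_num) {
  i <- which(x$atoms$name == "CA" & x$atoms$chain_id == chain &
               x$atoms$res_num == res_num)
  if (length(i) == 0L)
    stop(sprintf("no CA atom at %s:%d", chain, as.integer(res_num)))
  as.numeric(x$atoms[i[1], c("x", "y", "z")])
}

# ---------------------------------------------------------------------------
# PDB reading / writing (fixed-column v3.3 ATOM/HETATM/TER subset)
# ---------------------------------------------------------------------------

.pdb_field <- function(lines, from, to) substr(lines, from, to)

#' Read a PDB file (ATOM subset)
#'
#' Parses fixed-column ATOM (and optionally HETATM) records. Insertion codes
#' are rejected; alternate-location indicators other than `'A'` or blank are
#' dropped. Only the first MODEL of a multi-model file is kept (with a
#' warning). Waters and ligands (HETATM) are ignored unless `keep_hetatm`.
#'
#' @param text_or_path path to a PDB file, or a character scalar containing
#'   PDB text (detected by an embedded newline), or a character vector of
#'   lines.
#' @param keep_hetatm keep HETATM records (default FALSE).
#' @return structure3d
#' @export
read_pdb <- function(text_or_path, keep_hetatm = FALSE) {
  lines <- .as_lines(text_or_path)
  title <- ""
  ti <- grep("^TITLE ", lines)
  if (length(ti)) title <- trimws(substr(lines[ti[1]], 11, 80))
  # first MODEL only
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) {
    nmodel <- length(grep("^MODEL ", lines))
    if (nmodel > 1L)
      warning("multi-model file: keeping first MODEL only")
    lines2 <- lines[seq_len(endmdl[1] - 1L)]
    keep_idx <- seq_len(endmdl[1] - 1L)
  } else {
    lines2 <- lines
    keep_idx <- seq_along(lines)
  }
  rec <- .pdb_field(lines2, 1, 6)
  want <- rec == "ATOM  " | (keep_hetatm & rec == "HETATM")
  idx <- which(want)
  if (length(idx) == 0L)
    stop("no ATOM records found: empty structure")
  ln <- lines2[idx]
  lineno <- keep_idx[idx]
  short <- nchar(ln) < 54
  if (any(short))
    stop("malformed ATOM record (line too short for coordinate columns) at line ",
         lineno[which(short)[1]])
  icode <- .pdb_field(ln, 27, 27)
  if (any(icode != " "))
    stop("insertion codes are not supported (line ",
         lineno[which(icode != " ")[1]], ")")
  altloc <- .pdb_field(ln, 17, 17)
  keep <- altloc %in% c(" ", "A")
  ln <- ln[keep]; lineno <- lineno[keep]
  if (length(ln) == 0L)
    stop("no ATOM records left after altloc filtering: empty structure")
  num <- function(s, from, to, what) {
    v <- suppressWarnings(as.numeric(.pdb_field(s, from, to)))
    if (anyNA(v))
      stop(sprintf("malformed %s field at line %d", what,
                   lineno[which(is.na(v))[1]]))
    v
  }
  atoms <- data.frame(
    serial = as.integer(num(ln, 7, 11, "serial")),
    name = trimws(.pdb_field(ln, 13, 16)),
    element = trimws(.pdb_field(ln, 77, 78)),
    res_name = trimws(.pdb_field(ln, 18, 20)),
    chain_id = .pdb_field(ln, 22, 22),
    res_num = as.integer(num(ln, 23, 26, "residue number")),
    x = num(ln, 31, 38, "x coordinate"),
    y = num(ln, 39, 46, "y coordinate"),
    z = num(ln, 47, 54, "z coordinate"),
    stringsAsFactors = FALSE
  )
  # fall back: derive element from atom name when column 77-78 is blank
  blank <- atoms$element == ""
  if (any(blank))
    atoms$element[blank] <- substr(gsub("[0-9]", "", atoms$name[blank]), 1, 1)
  structure3d(atoms, title = title)
}

.as_lines <- function(text_or_path) {
  if (length(text_or_path) > 1L) return(text_or_path)
  if (grepl("\n", text_or_path, fixed = TRUE))
    return(strsplit(text_or_path, "\n", fixed = TRUE)[[1]])
  if (file.exists(text_or_path))
    return(readLines(text_or_path, warn = FALSE))
  # single line that looks like record text rather than a path
  if (grepl("^(ATOM|HETATM|TITLE|MODEL|REMARK|TER|END|#|[[:space:]]*[0-9.+-])",
            text_or_path))
    return(text_or_path)
  stop("file not found: ", text_or_path)
}

#' Write a structure as PDB text
#'
#' Emits fixed-column ATOM records (3-decimal coordinates), TER records at
#' chain boundaries and a final END. The output round-trips through
#' [read_pdb()].
#'
#' @param structure structure3d
#' @param path optional output file; if NULL the text is returned invisibly.
#' @return character vector of PDB lines (invisibly when `path` given)
#' @export
write_pdb <- function(structure, path = NULL) {
  a <- structure$atoms
  if (any(abs(as.matrix(a[c("x", "y", "z")])) >= 10000))
    stop("coordinate magnitude >= 10000 A cannot be represented in PDB columns")
  if (any(a$res_num > 9999L | a$res_num < -999L))
    stop("residue number outside PDB column range")
  name4 <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                  sprintf(" %-3s", a$name))
  rec <- sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 a$serial %% 100000L, name4, a$res_name, a$chain_id, a$res_num,
                 a$x, a$y, a$z, 1.0, 0.0, substr(a$element, 1, 2))
  # TER at chain changes
  out <- character(0)
  if (nzchar(structure$title))
    out <- sprintf("TITLE     %s", structure$title)
  chains <- a$chain_id
  brk <- which(chains[-1] != chains[-length(chains)])
  pieces <- split(seq_len(nrow(a)), cumsum(seq_len(nrow(a)) %in% (brk + 1L)))
  for (p in pieces) out <- c(out, rec[p], "TER")
  out <- c(out, "END")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

# ---------------------------------------------------------------------------
# SAXS 3-column text
# ---------------------------------------------------------------------------

#' Construct a SAXS curve
#' @param q scattering vector, 1/Angstrom, strictly increasing
#' @param I intensity (arbitrary units)
#' @param sigma per-point uncertainty, > 0
#' @return data.frame of class `saxs_curve`
#' @export
saxs_curve <- function(q, I, sigma) {
  if (length(q) != length(I) || length(q) != length(sigma))
    stop("q, I and sigma must have equal length")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (any(sigma <= 0)) stop("sigma must be positive")
  out <- data.frame(q = as.numeric(q), I = as.numeric(I),
                    sigma = as.numeric(sigma))
  class(out) <- c("saxs_curve", "data.frame")
  out
}

#' Read a 3-column SAXS .dat file
#'
#' Whitespace-separated `q I sigma` rows; `#` lines are comments; columns
#' beyond the third are ignored (beamline dialect drift). Rows with
#' `sigma <= 0` are dropped with a warning; q is sorted ascending if needed.
#'
#' @param text_or_path file path or text (as in [read_pdb()])
#' @return `saxs_curve`
#' @export
read_saxs_dat <- function(text_or_path) {
  lines <- .as_lines(text_or_path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[[:space:]]+")
  # permit a non-numeric header line
  is_num_row <- vapply(toks, function(tk)
    length(tk) >= 1 && !is.na(suppressWarnings(as.numeric(tk[1]))), logical(1))
  toks <- toks[is_num_row]
  if (length(toks) == 0L) stop("no numeric rows in SAXS file")
  ncols <- vapply(toks, length, integer(1))
  if (any(ncols == 2L))
    stop("2-column SAXS file: the sigma (uncertainty) column is missing")
  if (any(ncols < 3L))
    stop("SAXS rows must have at least 3 columns (q, I, sigma)")
  m <- t(vapply(toks, function(tk) as.numeric(tk[1:3]), numeric(3)))
  if (anyNA(m)) stop("non-numeric value in SAXS data row ",
                     which(apply(is.na(m), 1, any))[1])
  bad <- m[, 3] <= 0
  if (any(bad)) {
    warning(sum(bad), " row(s) with sigma <= 0 dropped")
    m <- m[!bad, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("fewer than 2 usable rows in SAXS file")
  if (is.unsorted(m[, 1], strictly = TRUE)) {
    warning("q not strictly increasing: sorting")
    m <- m[order(m[, 1]), , drop = FALSE]
    m <- m[!duplicated(m[, 1]), , drop = FALSE]
  }
  saxs_curve(m[, 1], m[, 2], m[, 3])
}

# ---------------------------------------------------------------------------
# Crosslink CSV
# ---------------------------------------------------------------------------

#' Construct a crosslink record table
#'
#' Pairs are unordered: each row is canonicalized so that
#' `(chain1, res1) <= (chain2, res2)`; duplicate pairs are collapsed keeping
#' the maximum score.
#'
#' @param chain1,res1,chain2,res2 residue addresses
#' @param score numeric match score (default 0)
#' @param is_decoy logical decoy flag (default FALSE)
#' @return data.frame of class `crosslinks`
#' @export
crosslinks <- function(chain1, res1, chain2, res2, score = 0,
                       is_decoy = FALSE) {
  n <- length(res1)
  df <- data.frame(chain1 = as.character(chain1), res1 = as.integer(res1),
                   chain2 = as.character(chain2), res2 = as.integer(res2),
                   score = rep_len(as.numeric(score), n),
                   is_decoy = rep_len(as.logical(is_decoy), n),
                   stringsAsFactors = FALSE)
  if (n > 0) {
    swap <- (df$chain2 < df$chain1) |
      (df$chain2 == df$chain1 & df$res2 < df$res1)
    if (any(swap)) {
      tmp <- df[swap, c("chain1", "res1")]
      df[swap, c("chain1", "res1")] <- df[swap, c("chain2", "res2")]
      df[swap, c("chain2", "res2")] <- tmp
    }
    key <- paste(df$chain1, df$res1, df$chain2, df$res2, df$is_decoy)
    if (anyDuplicated(key)) {
      df <- df[order(key, -df$score), ]
      df <- df[!duplicated(paste(df$chain1, df$res1, df$chain2, df$res2,
                                 df$is_decoy)), ]
      df <- df[order(df$chain1, df$res1, df$chain2, df$res2), ]
    }
  }
  rownames(df) <- NULL
  class(df) <- c("crosslinks", "data.frame")
  df
}

#' Read a crosslink CSV file
#'
#' Requires a header with columns `chain1,res1,chain2,res2`; optional
#' `score` (default 0) and `is_decoy` (default FALSE) columns. Unordered
#' duplicate pairs are collapsed keeping the maximum score.
#'
#' @param path CSV path
#' @return `crosslinks` table
#' @export
read_crosslinks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("chain1", "res1", "chain2", "res2")
  if (!all(need %in% names(df)))
    stop("crosslink CSV must have header columns: ",
         paste(need, collapse = ","))
  if (nrow(df) == 0L) {
    warning("empty crosslink file")
    return(crosslinks(character(0), integer(0), character(0), integer(0)))
  }
  for (col in c("res1", "res2")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(v) | v != round(v)
    if (any(bad))
      stop(sprintf("non-integer residue field '%s' at row %d", col,
                   which(bad)[1]))
    df[[col]] <- as.integer(v)
  }
  crosslinks(df$chain1, df$res1, df$chain2, df$res2,
             score = if ("score" %in% names(df)) df$score else 0,
             is_decoy = if ("is_decoy" %in% names(df))
               as.logical(df$is_decoy) else FALSE)
}

# ---------------------------------------------------------------------------
# Time-series trace tables
# ---------------------------------------------------------------------------

#' Construct a time-series trace table
#'
#' Column `t` (seconds, or degrees C for melt curves) plus one or more named
#' signal columns. Analyte concentrations (molar), where applicable, are
#' stored as the `conc` attribute (named by signal column).
#'
#' @param t time grid, strictly increasing
#' @param ... named numeric signal columns
#' @param conc optional named numeric vector of analyte concentrations (M)
#' @return data.frame of class `trace_table`
#' @export
trace_table <- function(t, ..., conc = NULL) {
  cols <- list(...)
  if (length(cols) == 1L && is.data.frame(cols[[1]])) cols <- as.list(cols[[1]])
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  n <- length(t)
  for (nm in names(cols))
    if (length(cols[[nm]]) != n) stop("column '", nm, "' length mismatch")
  out <- data.frame(t = as.numeric(t), cols, check.names = FALSE)
  if (!is.null(conc)) attr(out, "conc") <- conc
  class(out) <- c("trace_table", "data.frame")
  out
}

#' Read a time-series CSV (column `t` plus signal columns)
#' @param path CSV path
#' @return `trace_table`
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"t" %in% names(df)) stop("trace CSV must have a 't' column")
  if (nrow(df) < 10L) stop("at least 10 time points required")
  trace_table(df$t, df[setdiff(names(df), "t")])
}
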