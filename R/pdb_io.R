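#' Read a (multi-model) PDB file
#'
#' Fixed-column parser for ATOM/HETATM/MODEL/ENDMDL records. Both ATOM and
#' HETATM are kept. Alternate locations are resolved by highest occupancy,
#' then first occurrence; insertion codes are rejected. When SEG id columns
#' (73-76) are populated the segment name is used as the chain label (the
#' CHARMM/NAMD convention, where chains such as "H2A'" exceed the single
#' chainID column); otherwise the chainID column is used.
#'
#' @param path path to a PDB file.
#' @return A list of `md_structure`, one per MODEL (length 1 if no MODEL
#'   records).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model_open <- startsWith(rec, "MODEL")
  is_model_close <- startsWith(rec, "ENDMDL")
  if (!any(is_atom)) stop("empty input: no ATOM/HETATM records in ", path)

  model_id <- cumsum(is_model_open)
  has_models <- any(is_model_open)
  atom_lines <- which(is_atom)
  atom_model <- if (has_models) model_id[atom_lines] else rep(1L, length(atom_lines))
  if (has_models && any(atom_model == 0L)) {
    stop("ATOM record before first MODEL at line ", atom_lines[atom_model == 0L][1])
  }

  parse_block <- function(idx) {
    ln <- lines[idx]
    num <- function(s, what) {
      v <- suppressWarnings(as.numeric(s))
      bad <- which(is.na(v) | !nzchar(trimws(s)))
      if (length(bad) > 0) {
        stop(sprintf("malformed %s field at line %d", what, idx[bad[1]]))
      }
      v
    }
    serial <- num(substr(ln, 7, 11), "serial")
    name <- trimws(substr(ln, 13, 16))
    altloc <- substr(ln, 17, 17)
    resname <- trimws(substr(ln, 18, 21))
    chainid <- trimws(substr(ln, 22, 22))
    resid <- num(substr(ln, 23, 26), "resid")
    icode <- substr(ln, 27, 27)
    if (any(icode != " ")) {
      stop("insertion codes are not supported (line ",
           idx[which(icode != " ")[1]], ")")
    }
    x <- num(substr(ln, 31, 38), "x")
    y <- num(substr(ln, 39, 46), "y")
    z <- num(substr(ln, 47, 54), "z")
    occ_raw <- trimws(substr(ln, 55, 60))
    occ <- suppressWarnings(as.numeric(occ_raw))
    occ[is.na(occ)] <- 1
    segid <- trimws(substr(ln, 73, 76))
    element <- trimws(substr(ln, 77, 78))
    noel <- !nzchar(element)
    element[noel] <- substr(gsub("[^A-Za-z].*$", "", name[noel]), 1, 1)
    chain <- ifelse(nzchar(segid), segid, chainid)

    at <- data.frame(serial = as.integer(serial), name = name,
                     element = element, resname = resname,
                     resid = as.integer(resid), chain = chain,
                     stringsAsFactors = FALSE)
    xyz <- cbind(x = x, y = y, z = z)

    # alternate locations: keep highest occupancy, then first
    if (any(altloc != " ")) {
      key <- paste(at$chain, at$resid, at$name, sep = "\r")
      ord <- order(match(key, unique(key)), -occ, seq_along(key))
      keep_first <- !duplicated(key[ord])
      sel <- sort(ord[keep_first])
      at <- at[sel, , drop = FALSE]
      xyz <- xyz[sel, , drop = FALSE]
    }
    list(atoms = at, xyz = xyz)
  }

  models <- sort(unique(atom_model))
  title_lines <- lines[startsWith(rec, "TITLE")]
  title <- if (length(title_lines) > 0) trimws(substr(title_lines[1], 11, 80)) else ""
  out <- lapply(models, function(m) {
    b <- parse_block(atom_lines[atom_model == m])
    md_structure(b$atoms, b$xyz, title)
  })
  out
}

#' Write structures to a (multi-model) PDB file
#'
#' One MODEL/ENDMDL block per structure when more than one is given; a single
#' structure is written without MODEL records. Chain labels of one character
#' go to the chainID column; longer labels (segment-style names such as
#' "H2A'") additionally go to the SEG id columns 73-76 with chainID assigned
#' alphabetically per unique label, so [read_pdb()] round-trips them.
#'
#' @param structures an `md_structure` or list of them, sharing atom count and
#'   ordering.
#' @param path output path.
#' @param remarks optional character vector of REMARK payloads, one per
#'   structure (used e.g. to store docking scores).
#' @param force_models write MODEL/ENDMDL records even for a single structure.
#' @return The path, invisibly.
#' @export
write_pdb <- function(structures, path, remarks = NULL, force_models = FALSE) {
  if (inherits(structures, "md_structure")) structures <- list(structures)
  stopifnot(length(structures) >= 1)
  ref <- structures[[1]]$atoms
  for (s in structures) {
    stopifnot(inherits(s, "md_structure"))
    if (nrow(s$atoms) != nrow(ref) || !identical(s$atoms$name, ref$name)) {
      stop("all structures must share atom count and ordering")
    }
    if (any(abs(s$xyz) >= 1e5)) {
      stop("field overflow: coordinate magnitude >= 1e5 Angstrom")
    }
  }
  if (!is.null(remarks)) stopifnot(length(remarks) == length(structures))

  chains <- unique(ref$chain)
  long <- any(nchar(chains) > 1)
  chain_char <- if (long) stats::setNames(c(LETTERS, letters)[seq_along(chains)], chains)
                else stats::setNames(ifelse(nzchar(chains), chains, " "), chains)

  fmt_coord <- function(v) {
    out <- sprintf("%8.3f", v)
    wide <- nchar(out) > 8
    out[wide] <- sprintf("%8.2f", v[wide])
    out
  }
  body_for <- function(s) {
    a <- s$atoms
    nm <- a$name
    # atom-name column convention: 1-3 char names start at column 14
    nm4 <- ifelse(nchar(nm) >= 4, substr(nm, 1, 4), sprintf(" %-3s", nm))
    seg <- if (long) sprintf("%-4s", substr(a$chain, 1, 4)) else strrep(" ", 4)
    sprintf("ATOM  %5d %4s %-4s%1s%4d    %s%s%s%6.2f%6.2f      %4s%2s",
            a$serial %% 100000L, nm4, substr(a$resname, 1, 4),
            chain_char[a$chain], a$resid %% 10000L,
            fmt_coord(s$xyz[, 1]), fmt_coord(s$xyz[, 2]), fmt_coord(s$xyz[, 3]),
            1, 0, seg, sprintf("%2s", substr(a$element, 1, 2)))
  }

  lines <- character(0)
  if (nzchar(structures[[1]]$title)) {
    lines <- c(lines, sprintf("TITLE     %s", structures[[1]]$title))
  }
  multi <- length(structures) > 1 || force_models
  for (i in seq_along(structures)) {
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", i))
    if (!is.null(remarks) && nzchar(remarks[i])) {
      lines <- c(lines, sprintf("REMARK   1 %s", remarks[i]))
    }
    lines <- c(lines, body_for(structures[[i]]))
    if (multi) lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write an ensemble as a multi-model PDB
#' @param ens an `md_ensemble`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_ensemble_pdb <- function(ens, path) {
  stopifnot(inherits(ens, "md_ensemble"))
  structs <- lapply(ens$frames, function(f) {
    md_structure(ens$topology$atoms, f, ens$topology$title)
  })
  write_pdb(structs, path)
}

#' Read a multi-model PDB as an ensemble
#' @param path path to a multi-model PDB.
#' @param times optional frame times in ns (default 0, 1, 2, ...).
#' @return An `md_ensemble`.
#' @export
read_ensemble_pdb <- function(path, times = NULL) {
  structs <- read_pdb(path)
  md_ensemble(structs[[1]], lapply(structs, coords), times)
}

#' Write a pose set as a multi-model PDB with per-model score REMARKs
#'
#' Each pose becomes one MODEL; its docking score and receptor snapshot index
#' are stored in a `REMARK   1 SCORE: <s> SNAPSHOT: <i>` line, the usual way
#' docking engines annotate pose files.
#'
#' @param poses a `pose_set`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_pose_pdb <- function(poses, path) {
  stopifnot(inherits(poses, "pose_set"))
  m <- nrow(poses$atoms)
  at <- data.frame(serial = seq_len(m), name = poses$atoms$name,
                   element = poses$atoms$element, resname = "LIG",
                   resid = 1L, chain = "L", stringsAsFactors = FALSE)
  structs <- lapply(poses$coords, function(p) md_structure(at, p))
  write_pdb(structs, path, force_models = TRUE,
            remarks = sprintf("SCORE: %.4f SNAPSHOT: %d",
                              poses$score, poses$snapshot))
  invisible(path)
}

#' Read a pose set from a multi-model PDB with score REMARKs
#' @param path path written by [write_pose_pdb()] (or any multi-model PDB
#'   with `REMARK   1 SCORE:` lines; missing scores default to 0).
#' @return A `pose_set`.
#' @export
read_pose_pdb <- function(path) {
  structs <- read_pdb(path)
  lines <- readLines(path, warn = FALSE)
  model_id <- cumsum(startsWith(lines, "MODEL"))
  rem <- grepl("^REMARK   1 SCORE:", lines)
  score <- rep(0, length(structs))
  snapshot <- seq_along(structs)
  if (any(rem)) {
    mm <- model_id[rem]
    vals <- regmatches(lines[rem],
                       regexec("SCORE:\\s*(-?[0-9.]+)\\s*SNAPSHOT:\\s*([0-9]+)",
                               lines[rem]))
    for (k in seq_along(vals)) {
      if (length(vals[[k]]) == 3 && mm[k] >= 1 && mm[k] <= length(structs)) {
        score[mm[k]] <- as.numeric(vals[[k]][2])
        snapshot[mm[k]] <- as.integer(vals[[k]][3])
      }
    }
  }
  pose_set(lapply(structs, coords), score, snapshot,
           atoms = structs[[1]]$atoms[, c("name", "element")])
}

#' Read/write bound and free interaction-energy tables
#'
#' CSV layout: columns `frame`, `state` ("bound" or "free"), `e_vdw`, `e_el`
#' in kcal/mol.
#'
#' @param path CSV path.
#' @param dt frame spacing in ns attached to the returned series.
#' @return `read_energy_csv`: named list of [energy_series()] objects, one per
#'   state present in the file.
#' @export
read_energy_csv <- function(path, dt = 0.1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "state", "e_vdw", "e_el")
  if (!all(need %in% names(df))) {
    stop("energy CSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(split(df, df$state), function(d) {
    d <- d[order(d$frame), ]
    energy_series(d$e_vdw, d$e_el, state = d$state[1], dt = dt)
  })
  out
}

#' @rdname read_energy_csv
#' @param series a list of [energy_series()] objects to write.
#' @export
write_energy_csv <- function(series, path) {
  if (inherits(series, "energy_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(s) {
    data.frame(frame = seq_len(nrow(s$frames)), state = s$state,
               e_vdw = s$frames$e_vdw, e_el = s$frames$e_el)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
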