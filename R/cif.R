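#' Read a crystal structure from a CIF file
#'
#' Parses the first data block of a core-dictionary CIF: cell parameters,
#' symmetry operators (`_symmetry_equiv_pos_as_xyz` or
#' `_space_group_symop_operation_xyz`), atom sites with standard
#' uncertainties in parenthesis notation, occupancies and disorder flags,
#' `Z` and the ambient pressure (`_diffrn_ambient_pressure`, kPa, converted
#' to GPa). Fractional coordinates are wrapped into `[0, 1)`.
#'
#' @param path Path to a CIF file.
#' @param strict When `TRUE` (the default, mirroring survey-style curation),
#'   sites with occupancy below 1 or a disorder assembly raise a "disorder"
#'   error; when `FALSE` the highest-occupancy/ordered component is kept with
#'   a warning and occupancies are reset to 1.
#' @return A [crystal_structure()] (asymmetric unit; call [expand_to_cell()]
#'   for the full cell).
#' @export
read_cif <- function(path, strict = TRUE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  blk <- cif_block(lines)
  need_num <- function(tag) {
    v <- blk$values[[tag]]
    if (is.null(v)) abort(paste0("CIF format error: missing ", tag))
    parse_cif_number(v)[1]
  }
  cell <- tryCatch(
    unit_cell(
      need_num("_cell_length_a"), need_num("_cell_length_b"), need_num("_cell_length_c"),
      need_num("_cell_angle_alpha"), need_num("_cell_angle_beta"), need_num("_cell_angle_gamma")
    ),
    error = function(e) abort(paste0("CIF format error: unparsable cell (", conditionMessage(e), ")"))
  )
  symops <- cif_symops(blk)
  sites <- cif_sites(blk)
  if (is.null(sites) || !nrow(sites)) abort("no coordinates: CIF contains no atom sites")
  bad <- !is.finite(sites$fx) | !is.finite(sites$fy) | !is.finite(sites$fz)
  if (any(bad)) {
    abort(paste0("no coordinates: site(s) without coordinates: ",
                 paste(sites$label[bad], collapse = ", ")))
  }
  disordered <- sites$occ < 1 | !(sites$disorder %in% c(".", "", "1", NA))
  if (any(disordered)) {
    if (strict) {
      abort(paste0("disorder: site(s) with partial occupancy or disorder assembly: ",
                   paste(sites$label[disordered], collapse = ", ")))
    }
    warn("disordered sites present; keeping ordered/major component and resetting occupancies to 1")
    keep_grp <- sites$disorder %in% c(".", "", "1", NA)
    sites <- sites[keep_grp, , drop = FALSE]
    sites$occ <- 1
    if (!nrow(sites)) abort("disorder: no ordered component left after filtering")
  }
  Z <- if (!is.null(blk$values[["_cell_formula_units_z"]])) {
    parse_cif_number(blk$values[["_cell_formula_units_z"]])[1]
  } else NA_real_
  pressure <- NA_real_
  for (tag in c("_diffrn_ambient_pressure", "_diffrn_ambient_pressure_gpa")) {
    if (!is.null(blk$values[[tag]])) {
      p <- parse_cif_number(blk$values[[tag]])[1]
      pressure <- if (tag == "_diffrn_ambient_pressure") p / 1e6 else p
      break
    }
  }
  crystal_structure(
    cell,
    tibble(
      label = sites$label, element = sites$element,
      fx = sites$fx, fy = sites$fy, fz = sites$fz,
      su_x = sites$su_x, su_y = sites$su_y, su_z = sites$su_z,
      occ = sites$occ
    ),
    symops = symops, Z = Z, pressure = pressure, id = blk$name
  )
}

# ---- low-level CIF machinery -------------------------------------------

# first data block: returns list(name, values = named list of scalars,
# loops = list of data frames keyed by tag sets)
cif_block <- function(lines) {
  # drop full-line comments and semicolon text blocks (not needed here)
  out <- character(0)
  in_text <- FALSE
  for (ln in lines) {
    if (startsWith(ln, ";")) { in_text <- !in_text; next }
    if (in_text) next
    if (grepl("^\\s*#", ln)) next
    out <- c(out, ln)
  }
  lines <- out
  starts <- grep("^data_", lines)
  if (!length(starts)) abort("CIF format error: no data block")
  name <- sub("^data_", "", lines[starts[1]])
  end <- if (length(starts) > 1) starts[2] - 1 else length(lines)
  body <- lines[(starts[1] + 1):end]
  values <- list()
  loops <- list()
  i <- 1
  n <- length(body)
  while (i <= n) {
    ln <- trimws(body[i])
    if (!nzchar(ln)) { i <- i + 1; next }
    if (grepl("^loop_", ln, ignore.case = TRUE)) {
      i <- i + 1
      tags <- character(0)
      while (i <= n && grepl("^\\s*_", body[i])) {
        tags <- c(tags, strsplit(trimws(body[i]), "\\s+")[[1]][1])
        i <- i + 1
      }
      toks <- character(0)
      while (i <= n) {
        lt <- trimws(body[i])
        if (!nzchar(lt)) { i <- i + 1; next }
        if (grepl("^(_|loop_|data_)", lt, ignore.case = TRUE)) break
        toks <- c(toks, cif_tokens(lt))
        i <- i + 1
      }
      if (length(tags) && length(toks) >= length(tags)) {
        nr <- length(toks) %/% length(tags)
        m <- matrix(toks[seq_len(nr * length(tags))], ncol = length(tags), byrow = TRUE)
        df <- as.data.frame(m, stringsAsFactors = FALSE)
        names(df) <- tolower(tags)
        loops[[length(loops) + 1]] <- df
      }
      next
    }
    if (startsWith(ln, "_")) {
      toks <- cif_tokens(ln)
      tag <- tolower(toks[1])
      if (length(toks) >= 2) {
        values[[tag]] <- toks[2]
      } else if (i < n) {
        values[[tag]] <- trimws(body[i + 1])
        i <- i + 1
      }
    }
    i <- i + 1
  }
  list(name = name, values = values, loops = loops)
}

# split a CIF line into tokens, honouring single/double quotes
cif_tokens <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  toks <- regmatches(line, list(m))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

cif_symops <- function(blk) {
  tags <- c("_symmetry_equiv_pos_as_xyz", "_space_group_symop_operation_xyz")
  for (lp in blk$loops) {
    hit <- intersect(tags, names(lp))
    if (length(hit)) {
      ops <- lp[[hit[1]]]
      # validate now so a bad operator fails at read time
      lapply(ops, parse_symop)
      return(ops)
    }
  }
  for (tag in tags) {
    if (!is.null(blk$values[[tag]])) {
      op <- blk$values[[tag]]
      parse_symop(op)
      return(op)
    }
  }
  "x, y, z"
}

cif_sites <- function(blk) {
  lp <- NULL
  for (cand in blk$loops) {
    if ("_atom_site_fract_x" %in% names(cand) ||
        "_atom_site_label" %in% names(cand)) {
      lp <- cand
      break
    }
  }
  if (is.null(lp)) return(NULL)
  if (!all(c("_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z") %in% names(lp))) {
    abort("no coordinates: atom site loop lacks fractional coordinates")
  }
  label <- lp[["_atom_site_label"]] %||% paste0("A", seq_len(nrow(lp)))
  fx <- vapply(lp[["_atom_site_fract_x"]], parse_cif_number, numeric(2))
  fy <- vapply(lp[["_atom_site_fract_y"]], parse_cif_number, numeric(2))
  fz <- vapply(lp[["_atom_site_fract_z"]], parse_cif_number, numeric(2))
  element <- lp[["_atom_site_type_symbol"]]
  if (is.null(element)) element <- guess_element(label) else element <- clean_element(element)
  occ <- if (!is.null(lp[["_atom_site_occupancy"]])) {
    vapply(lp[["_atom_site_occupancy"]], function(s) parse_cif_number(s)[1], numeric(1))
  } else rep(1, nrow(lp))
  occ[!is.finite(occ)] <- 1
  disorder <- lp[["_atom_site_disorder_group"]] %||% rep(".", nrow(lp))
  data.frame(
    label = label, element = element,
    fx = fx[1, ], fy = fy[1, ], fz = fz[1, ],
    su_x = fx[2, ], su_y = fy[2, ], su_z = fz[2, ],
    occ = occ, disorder = disorder,
    stringsAsFactors = FALSE
  )
}

#' Parse a CIF numeric value with parenthesized standard uncertainty
#'
#' `"0.1234(5)"` parses to value 0.1234 with su 0.0005; a bare number has
#' su 0; `"."` and `"?"` parse to `NA`.
#'
#' @param s A character scalar.
#' @return Numeric length-2 vector `c(value, su)`.
#' @export
parse_cif_number <- function(s) {
  s <- trimws(s)
  if (s %in% c(".", "?", "")) return(c(NA_real_, 0))
  m <- regmatches(s, regexec("^([+-]?[0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)(?:\\(([0-9]+)\\))?$", s))[[1]]
  if (length(m) < 2 || !nzchar(m[2])) return(c(NA_real_, 0))
  val <- as.numeric(m[2])
  su <- 0
  if (length(m) >= 3 && nzchar(m[3])) {
    dec <- if (grepl("\\.", m[2])) nchar(sub("^[^.]*\\.", "", sub("[eE].*$", "", m[2]))) else 0
    su <- as.numeric(m[3]) * 10^(-dec)
  }
  c(val, su)
}

guess_element <- function(labels) {
  known <- vdw_radii()$element
  vapply(labels, function(lb) {
    alpha <- regmatches(lb, regexpr("^[A-Za-z]+", lb))
    if (!length(alpha)) return("X")
    alpha <- alpha[[1]]
    two <- if (nchar(alpha) >= 2) {
      paste0(toupper(substr(alpha, 1, 1)), tolower(substr(alpha, 2, 2)))
    } else ""
    if (nzchar(two) && two %in% known) return(two)
    toupper(substr(alpha, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}

clean_element <- function(el) {
  el <- gsub("[0-9+-]", "", el)
  paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)))
}

#' Write a crystal structure to a CIF file
#'
#' Emits a minimal core-dictionary CIF (cell, symmetry operator loop, atom
#' site loop) with coordinate standard uncertainties in parenthesis notation
#' when present. Round-trips through [read_cif()].
#'
#' @param structure A [crystal_structure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cif <- function(structure, path) {
  stopifnot(inherits(structure, "crystal_structure"))
  at <- structure$atoms
  cell <- structure$cell
  id <- if (nzchar(structure$id)) gsub("\\s+", "_", structure$id) else "voidpart"
  lines <- c(
    paste0("data_", id),
    sprintf("_cell_length_a %.6f", cell$a),
    sprintf("_cell_length_b %.6f", cell$b),
    sprintf("_cell_length_c %.6f", cell$c),
    sprintf("_cell_angle_alpha %.6f", cell$alpha),
    sprintf("_cell_angle_beta %.6f", cell$beta),
    sprintf("_cell_angle_gamma %.6f", cell$gamma)
  )
  if (is.finite(structure$Z)) {
    lines <- c(lines, sprintf("_cell_formula_units_Z %g", structure$Z))
  }
  if (is.finite(structure$pressure)) {
    lines <- c(lines, sprintf("_diffrn_ambient_pressure %.6f", structure$pressure * 1e6))
  }
  lines <- c(
    lines,
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    sprintf("'%s'", structure$symops),
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "_atom_site_occupancy",
    sprintf(
      "%s %s %s %s %s %.4f",
      at$label, at$element,
      format_su(at$fx, at$su_x), format_su(at$fy, at$su_y), format_su(at$fz, at$su_z),
      at$occ
    )
  )
  writeLines(lines, path)
  invisible(path)
}

# format a value with CIF parenthesis su notation
format_su <- function(v, su) {
  mapply(function(vi, si) {
    if (!is.finite(si) || si <= 0) return(sprintf("%.6f", vi))
    d <- -floor(log10(si))
    si_int <- round(si * 10^d)
    if (si_int >= 10) { d <- d - 1; si_int <- round(si * 10^d) }
    d <- max(d, 0)
    sprintf("%.*f(%d)", d, vi, si_int)
  }, v, su, USE.NAMES = FALSE)
}
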