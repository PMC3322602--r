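# ---- CIF tokenizer ----------------------------------------------------------

cif_tokenize <- function(lines) {
  toks <- character(0); lns <- integer(0)
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- lines[i]
    if (startsWith(line, ";")) {
      # multiline text value
      buf <- substring(line, 2L)
      i <- i + 1L
      while (i <= n && !startsWith(lines[i], ";")) {
        buf <- paste0(buf, "\n", lines[i]); i <- i + 1L
      }
      toks <- c(toks, paste0("\x01", buf))  # marker: literal value
      lns <- c(lns, i)
      i <- i + 1L
      next
    }
    m <- gregexpr("('[^']*'|\"[^\"]*\"|#|\\S+)", line)[[1]]
    if (m[1] != -1L) {
      pieces <- regmatches(line, gregexpr("('[^']*'|\"[^\"]*\"|#|\\S+)", line))[[1]]
      for (p in pieces) {
        if (startsWith(p, "#")) break
        toks <- c(toks, p); lns <- c(lns, i)
      }
    }
    i <- i + 1L
  }
  list(tokens = toks, lines = lns)
}

cif_unquote <- function(tok) {
  if (startsWith(tok, "\x01")) return(substring(tok, 2L))
  n <- nchar(tok)
  if (n >= 2L && ((startsWith(tok, "'") && endsWith(tok, "'")) ||
                    (startsWith(tok, "\"") && endsWith(tok, "\""))))
    substr(tok, 2L, n - 1L)
  else tok
}

is_tag <- function(tok) startsWith(tok, "_")
is_reserved <- function(tok)
  grepl("^(data_|loop_$|global_$|save_|stop_$)", tolower(tok))

# Parse a CIF document into blocks of categories.  Each category is a
# data.frame of character columns (items), whether it came from a loop or
# from scalar tag-value pairs.
parse_cif <- function(lines) {
  tk <- cif_tokenize(lines)
  toks <- tk$tokens; lns <- tk$lines
  blocks <- list()
  cur_name <- NULL
  cur_cats <- list()
  cat_order <- character(0)
  flush <- function() {
    if (!is.null(cur_name))
      blocks[[length(blocks) + 1L]] <<- list(name = cur_name,
                                             categories = cur_cats[cat_order])
  }
  add_rows <- function(tags, values, line) {
    cat <- sub("\\..*$", "", sub("^_", "", tags[1]))
    items <- sub("^[^.]*\\.", "", tags)
    if (length(values) %% length(tags) != 0L)
      stop("malformed loop near line ", line, ": ", length(values),
           " values for ", length(tags), " tags")
    m <- matrix(vapply(values, cif_unquote, character(1)),
                ncol = length(tags), byrow = TRUE)
    df <- as.data.frame(m, stringsAsFactors = FALSE)
    names(df) <- items
    if (!is.null(cur_cats[[cat]])) {
      cur_cats[[cat]] <<- rbind(cur_cats[[cat]], df)
    } else {
      cur_cats[[cat]] <<- df
      cat_order <<- c(cat_order, cat)
    }
  }
  i <- 1L
  n <- length(toks)
  while (i <= n) {
    t <- toks[i]
    if (grepl("^data_", t, ignore.case = TRUE)) {
      flush()
      cur_name <- substring(t, 6L)
      cur_cats <- list(); cat_order <- character(0)
      i <- i + 1L
    } else if (tolower(t) == "loop_") {
      i <- i + 1L
      tags <- character(0)
      while (i <= n && is_tag(toks[i])) { tags <- c(tags, toks[i]); i <- i + 1L }
      if (!length(tags)) stop("loop_ without tags near line ", lns[min(i, n)])
      vals <- character(0)
      start_line <- lns[min(i, n)]
      while (i <= n && !is_tag(toks[i]) && !is_reserved(toks[i])) {
        vals <- c(vals, toks[i]); i <- i + 1L
      }
      add_rows(tags, vals, start_line)
    } else if (is_tag(t)) {
      if (i + 1L > n || is_tag(toks[i + 1L]) || is_reserved(toks[i + 1L]))
        stop("tag ", t, " without value near line ", lns[i])
      add_rows(t, toks[i + 1L], lns[i])
      i <- i + 2L
    } else {
      stop("unexpected token '", t, "' near line ", lns[i])
    }
  }
  flush()
  blocks
}

na_dot <- function(x) ifelse(x == "." | x == "?", NA_character_, x)
num_or_na <- function(x) suppressWarnings(as.numeric(na_dot(x)))
int_or_na <- function(x) suppressWarnings(as.integer(round(as.numeric(na_dot(x)))))

sign_from_cif <- function(x) {
  x <- tolower(as.character(x))
  out <- rep("both", length(x))
  out[x %in% c("positiv", "positive")] <- "positive"
  out[x %in% c("negativ", "negative")] <- "negative"
  out
}
sign_to_cif <- function(x)
  c(positive = "positiv", negative = "negativ", both = "both")[x]

# Default sigmas adopted (and flagged) when an entry omits esd fields.
DEFAULT_BOND_SIGMA <- 0.02
DEFAULT_ANGLE_SIGMA <- 3.0

# ---- block -> entry converters ---------------------------------------------

# Safe accessor for an index-list row field: NA when the row or the column
# is absent.
list_field <- function(row, field) {
  if (is.null(row) || is.null(row[[field]]) || is.na(row[[field]]))
    NA_character_
  else as.character(row[[field]])
}

cat_or_empty <- function(cats, name, items) {
  df <- cats[[name]]
  if (is.null(df)) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(items)),
                                        items), stringsAsFactors = FALSE)
    return(df)
  }
  for (it in items) if (!it %in% names(df)) df[[it]] <- NA_character_
  df[, items, drop = FALSE]
}

monomer_from_block <- function(block, list_row = NULL) {
  cats <- block$categories
  code <- sub("^comp_", "", block$name)
  at <- cat_or_empty(cats, "chem_comp_atom",
                     c("comp_id", "atom_id", "type_symbol", "type_energy",
                       "partial_charge"))
  atoms <- data.frame(name = at$atom_id,
                      element = normalize_element(at$type_symbol),
                      energy_type = na_dot(at$type_energy),
                      charge = ifelse(is.na(int_or_na(at$partial_charge)), 0L,
                                      int_or_na(at$partial_charge)),
                      parent_ref = at$atom_id, stringsAsFactors = FALSE)
  bd <- cat_or_empty(cats, "chem_comp_bond",
                     c("comp_id", "atom_id_1", "atom_id_2", "type",
                       "value_dist", "value_dist_esd"))
  flagged <- character(0)
  sig <- num_or_na(bd$value_dist_esd)
  tgt <- num_or_na(bd$value_dist)
  if (any(is.na(sig) & !is.na(tgt))) {
    flagged <- c(flagged, "bond esd defaulted")
    sig[is.na(sig) & !is.na(tgt)] <- DEFAULT_BOND_SIGMA
  }
  bonds <- data.frame(atom1 = bd$atom_id_1, atom2 = bd$atom_id_2,
                      order = tolower(bd$type), target = tgt, sigma = sig,
                      stringsAsFactors = FALSE)
  an <- cat_or_empty(cats, "chem_comp_angle",
                     c("comp_id", "atom_id_1", "atom_id_2", "atom_id_3",
                       "value_angle", "value_angle_esd"))
  asig <- num_or_na(an$value_angle_esd)
  if (any(is.na(asig)) && nrow(an)) {
    flagged <- c(flagged, "angle esd defaulted")
    asig[is.na(asig)] <- DEFAULT_ANGLE_SIGMA
  }
  angles <- data.frame(atom1 = an$atom_id_1, atom2 = an$atom_id_2,
                       atom3 = an$atom_id_3, target = num_or_na(an$value_angle),
                       sigma = asig, stringsAsFactors = FALSE)
  tr <- cat_or_empty(cats, "chem_comp_tor",
                     c("comp_id", "id", "atom_id_1", "atom_id_2", "atom_id_3",
                       "atom_id_4", "value_angle", "value_angle_esd", "period"))
  torsions <- data.frame(id = tr$id, atom1 = tr$atom_id_1, atom2 = tr$atom_id_2,
                         atom3 = tr$atom_id_3, atom4 = tr$atom_id_4,
                         target = num_or_na(tr$value_angle),
                         sigma = num_or_na(tr$value_angle_esd),
                         period = int_or_na(tr$period), stringsAsFactors = FALSE)
  chm <- cat_or_empty(cats, "chem_comp_chir",
                      c("comp_id", "id", "atom_id_centre", "atom_id_1",
                        "atom_id_2", "atom_id_3", "volume_sign"))
  chirals <- data.frame(id = chm$id, centre = chm$atom_id_centre,
                        atom1 = chm$atom_id_1, atom2 = chm$atom_id_2,
                        atom3 = chm$atom_id_3,
                        sign = sign_from_cif(chm$volume_sign),
                        stringsAsFactors = FALSE)
  pl <- cat_or_empty(cats, "chem_comp_plane_atom",
                     c("comp_id", "plane_id", "atom_id", "dist_esd"))
  planes <- data.frame(plane_id = pl$plane_id, atom_id = pl$atom_id,
                       dist_esd = num_or_na(pl$dist_esd),
                       stringsAsFactors = FALSE)
  lvl_field <- list_field(list_row, "desc_level")
  level <- if (!is.na(lvl_field) && lvl_field == "M") "minimal"
  else if (nrow(angles) || any(!is.na(bonds$target))) "complete" else "minimal"
  nm_field <- list_field(list_row, "name")
  grp_field <- list_field(list_row, "group")
  desc <- monomer_description(
    code = code,
    name = if (!is.na(nm_field)) nm_field else "",
    group = if (!is.na(grp_field)) grp_field else "non-polymer",
    level = level, atoms = atoms, bonds = bonds, angles = angles,
    torsions = torsions, chirals = chirals, planes = planes)
  attr(desc, "flagged_defaults") <- flagged
  known <- c("chem_comp_atom", "chem_comp_bond", "chem_comp_angle",
             "chem_comp_tor", "chem_comp_chir", "chem_comp_plane_atom",
             "chem_comp")
  attr(desc, "extra_categories") <- cats[setdiff(names(cats), known)]
  desc
}

mod_from_block <- function(block, list_row = NULL) {
  cats <- block$categories
  id <- sub("^mod_", "", block$name)
  at <- cat_or_empty(cats, "chem_mod_atom",
                     c("mod_id", "function", "atom_id", "new_atom_id",
                       "new_type_symbol", "new_type_energy", "new_charge"))
  atoms <- data.frame(fun = at[["function"]], atom_id = at$atom_id,
                      new_atom_id = na_dot(at$new_atom_id),
                      new_type_symbol = na_dot(at$new_type_symbol),
                      new_type_energy = na_dot(at$new_type_energy),
                      new_charge = int_or_na(at$new_charge),
                      stringsAsFactors = FALSE)
  bd <- cat_or_empty(cats, "chem_mod_bond",
                     c("mod_id", "function", "atom_id_1", "atom_id_2",
                       "new_type", "new_value_dist", "new_value_dist_esd"))
  bonds <- data.frame(fun = bd[["function"]], atom1 = bd$atom_id_1,
                      atom2 = bd$atom_id_2, new_order = na_dot(tolower(bd$new_type)),
                      new_target = num_or_na(bd$new_value_dist),
                      new_sigma = num_or_na(bd$new_value_dist_esd),
                      stringsAsFactors = FALSE)
  an <- cat_or_empty(cats, "chem_mod_angle",
                     c("mod_id", "function", "atom_id_1", "atom_id_2",
                       "atom_id_3", "new_value_angle", "new_value_angle_esd"))
  angles <- data.frame(fun = an[["function"]], atom1 = an$atom_id_1,
                       atom2 = an$atom_id_2, atom3 = an$atom_id_3,
                       new_target = num_or_na(an$new_value_angle),
                       new_sigma = num_or_na(an$new_value_angle_esd),
                       stringsAsFactors = FALSE)
  tr <- cat_or_empty(cats, "chem_mod_tor",
                     c("mod_id", "function", "id", "atom_id_1", "atom_id_2",
                       "atom_id_3", "atom_id_4", "new_value_angle",
                       "new_value_angle_esd", "new_period"))
  torsions <- data.frame(fun = tr[["function"]], id = tr$id,
                         atom1 = tr$atom_id_1, atom2 = tr$atom_id_2,
                         atom3 = tr$atom_id_3, atom4 = tr$atom_id_4,
                         new_target = num_or_na(tr$new_value_angle),
                         new_sigma = num_or_na(tr$new_value_angle_esd),
                         new_period = int_or_na(tr$new_period),
                         stringsAsFactors = FALSE)
  ch <- cat_or_empty(cats, "chem_mod_chir",
                     c("mod_id", "function", "id", "atom_id_centre",
                       "atom_id_1", "atom_id_2", "atom_id_3",
                       "new_volume_sign"))
  chirals <- data.frame(fun = ch[["function"]], id = ch$id,
                        centre = ch$atom_id_centre, atom1 = ch$atom_id_1,
                        atom2 = ch$atom_id_2, atom3 = ch$atom_id_3,
                        new_sign = sign_from_cif(ch$new_volume_sign),
                        stringsAsFactors = FALSE)
  pl <- cat_or_empty(cats, "chem_mod_plane_atom",
                     c("mod_id", "function", "plane_id", "atom_id",
                       "new_dist_esd"))
  planes <- data.frame(fun = pl[["function"]], plane_id = pl$plane_id,
                       atom_id = pl$atom_id,
                       new_dist_esd = num_or_na(pl$new_dist_esd),
                       stringsAsFactors = FALSE)
  modification_entry(
    id = id,
    parent = if (!is.na(list_field(list_row, "comp_id")))
      list_field(list_row, "comp_id") else ".",
    group = list_field(list_row, "group_id"),
    name = if (!is.na(list_field(list_row, "name")))
      list_field(list_row, "name") else "",
    atoms = atoms, bonds = bonds, angles = angles, torsions = torsions,
    chirals = chirals, planes = planes)
}

link_from_block <- function(block, list_row = NULL) {
  cats <- block$categories
  id <- sub("^link_", "", block$name)
  bd <- cat_or_empty(cats, "chem_link_bond",
                     c("link_id", "atom_1_comp_id", "atom_id_1",
                       "atom_2_comp_id", "atom_id_2", "type", "value_dist",
                       "value_dist_esd"))
  bonds <- data.frame(comp1 = int_or_na(bd$atom_1_comp_id), atom1 = bd$atom_id_1,
                      comp2 = int_or_na(bd$atom_2_comp_id), atom2 = bd$atom_id_2,
                      order = tolower(bd$type), target = num_or_na(bd$value_dist),
                      sigma = num_or_na(bd$value_dist_esd),
                      stringsAsFactors = FALSE)
  an <- cat_or_empty(cats, "chem_link_angle",
                     c("link_id", "atom_1_comp_id", "atom_id_1",
                       "atom_2_comp_id", "atom_id_2", "atom_3_comp_id",
                       "atom_id_3", "value_angle", "value_angle_esd"))
  angles <- data.frame(comp1 = int_or_na(an$atom_1_comp_id), atom1 = an$atom_id_1,
                       comp2 = int_or_na(an$atom_2_comp_id), atom2 = an$atom_id_2,
                       comp3 = int_or_na(an$atom_3_comp_id), atom3 = an$atom_id_3,
                       target = num_or_na(an$value_angle),
                       sigma = num_or_na(an$value_angle_esd),
                       stringsAsFactors = FALSE)
  tr <- cat_or_empty(cats, "chem_link_tor",
                     c("link_id", "id", "atom_1_comp_id", "atom_id_1",
                       "atom_2_comp_id", "atom_id_2", "atom_3_comp_id",
                       "atom_id_3", "atom_4_comp_id", "atom_id_4",
                       "value_angle", "value_angle_esd", "period"))
  torsions <- data.frame(id = tr$id,
                         comp1 = int_or_na(tr$atom_1_comp_id), atom1 = tr$atom_id_1,
                         comp2 = int_or_na(tr$atom_2_comp_id), atom2 = tr$atom_id_2,
                         comp3 = int_or_na(tr$atom_3_comp_id), atom3 = tr$atom_id_3,
                         comp4 = int_or_na(tr$atom_4_comp_id), atom4 = tr$atom_id_4,
                         target = num_or_na(tr$value_angle),
                         sigma = num_or_na(tr$value_angle_esd),
                         period = int_or_na(tr$period), stringsAsFactors = FALSE)
  ch <- cat_or_empty(cats, "chem_link_chir",
                     c("link_id", "id", "atom_centre_comp_id", "atom_id_centre",
                       "atom_1_comp_id", "atom_id_1", "atom_2_comp_id",
                       "atom_id_2", "atom_3_comp_id", "atom_id_3",
                       "volume_sign"))
  chirals <- data.frame(id = ch$id, comp_centre = int_or_na(ch$atom_centre_comp_id),
                        centre = ch$atom_id_centre,
                        comp1 = int_or_na(ch$atom_1_comp_id), atom1 = ch$atom_id_1,
                        comp2 = int_or_na(ch$atom_2_comp_id), atom2 = ch$atom_id_2,
                        comp3 = int_or_na(ch$atom_3_comp_id), atom3 = ch$atom_id_3,
                        sign = sign_from_cif(ch$volume_sign),
                        stringsAsFactors = FALSE)
  pl <- cat_or_empty(cats, "chem_link_plane",
                     c("link_id", "plane_id", "atom_comp_id", "atom_id",
                       "dist_esd"))
  planes <- data.frame(plane_id = pl$plane_id, comp = int_or_na(pl$atom_comp_id),
                       atom_id = pl$atom_id, dist_esd = num_or_na(pl$dist_esd),
                       stringsAsFactors = FALSE)
  lr <- function(field, default = "") {
    v <- list_field(list_row, field)
    if (is.na(v)) default else v
  }
  link_entry(id = id,
             comp1 = lr("comp_id_1"), mod1 = lr("mod_id_1"),
             group1 = lr("group_comp_1"),
             comp2 = lr("comp_id_2"), mod2 = lr("mod_id_2"),
             group2 = lr("group_comp_2"), name = lr("name"),
             bonds = bonds, angles = angles, torsions = torsions,
             chirals = chirals, planes = planes)
}

#' Read a restraint library from CIF
#'
#' Parses a restraint-dictionary CIF document: `data_comp_list`,
#' `data_mod_list` and `data_link_list` index blocks plus per-entry
#' `data_comp_<CODE>`, `data_mod_<ID>` and `data_link_<ID>` blocks.
#' List blocks are cross-checked against entry blocks (a list row whose
#' entry block is missing is a consistency error).  Blocks that do not
#' follow the dialect's naming scheme are preserved opaquely and re-emitted
#' by [write_library()].  Missing esd fields are filled with documented
#' defaults (0.02 angstrom for bonds, 3.0 degrees for angles) and flagged
#' on the entry.
#'
#' @param text A file path, a single string, or a character vector of lines.
#' @param provenance Provenance label for the entries ("standard" or
#'   "additional").
#' @return A [restraint_library()].
#' @export
read_library <- function(text, provenance = "standard") {
  lines <- if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    readLines(text) else if (length(text) == 1L) strsplit(text, "\n")[[1]] else text
  blocks <- parse_cif(lines)
  bnames <- vapply(blocks, `[[`, character(1), "name")

  list_of <- function(block_name, cat, id_item) {
    i <- match(block_name, bnames)
    if (is.na(i)) return(NULL)
    df <- blocks[[i]]$categories[[cat]]
    if (is.null(df)) return(df)
    for (nm in names(df)) df[[nm]] <- na_dot(df[[nm]])
    df
  }
  comp_list <- list_of("comp_list", "chem_comp", "id")
  mod_list <- list_of("mod_list", "chem_mod", "id")
  link_list <- list_of("link_list", "chem_link", "id")

  lib <- restraint_library(provenance = provenance)
  lib$has_comp_list <- !is.na(match("comp_list", bnames))
  lib$has_mod_list <- !is.na(match("mod_list", bnames))
  lib$has_link_list <- !is.na(match("link_list", bnames))

  for (b in blocks) {
    nm <- b$name
    if (nm %in% c("comp_list", "mod_list", "link_list")) next
    if (startsWith(nm, "comp_")) {
      code <- sub("^comp_", "", nm)
      row <- if (!is.null(comp_list)) comp_list[comp_list$id == code, , drop = FALSE] else NULL
      row <- if (!is.null(row) && nrow(row)) as.list(row[1, ]) else NULL
      lib$monomers[[code]] <- monomer_from_block(b, row)
      lib$provenance[code] <- provenance
    } else if (startsWith(nm, "mod_")) {
      id <- sub("^mod_", "", nm)
      row <- if (!is.null(mod_list)) mod_list[mod_list$id == id, , drop = FALSE] else NULL
      row <- if (!is.null(row) && nrow(row)) as.list(row[1, ]) else NULL
      lib$modifications[[id]] <- mod_from_block(b, row)
      lib$provenance[id] <- provenance
    } else if (startsWith(nm, "link_")) {
      id <- sub("^link_", "", nm)
      row <- if (!is.null(link_list)) link_list[link_list$id == id, , drop = FALSE] else NULL
      row <- if (!is.null(row) && nrow(row)) as.list(row[1, ]) else NULL
      lib$links[[id]] <- link_from_block(b, row)
      lib$provenance[id] <- provenance
    } else {
      lib$opaque[[nm]] <- b$categories
    }
  }

  for (spec in list(list(comp_list, "id", lib$monomers, "comp_list"),
                    list(mod_list, "id", lib$modifications, "mod_list"),
                    list(link_list, "id", lib$links, "link_list"))) {
    if (is.null(spec[[1]])) next
    missing <- setdiff(spec[[1]][[spec[[2]]]], names(spec[[3]]))
    if (length(missing))
      stop("consistency error: ", spec[[4]], " references missing entry block(s): ",
           paste(missing, collapse = ", "))
  }
  lib
}

# ---- writer -----------------------------------------------------------------

cif_quote <- function(x) {
  x <- as.character(x)
  out <- x
  out[is.na(x) | !nzchar(x)] <- "."
  need <- !is.na(x) & nzchar(x) &
    (grepl("[ \t']", x) | startsWith(x, "_") | startsWith(x, "#"))
  has_sq <- need & grepl("'", x)
  out[need & !has_sq] <- paste0("'", x[need & !has_sq], "'")
  out[has_sq] <- paste0("\"", gsub("\"", "", x[has_sq]), "\"")
  out
}

fmt_len <- function(x) ifelse(is.na(x), ".", sprintf("%.3f", x))
fmt_deg <- function(x) ifelse(is.na(x), ".", sprintf("%.2f", x))
fmt_int <- function(x) ifelse(is.na(x), ".", sprintf("%d", as.integer(x)))

emit_loop <- function(out, cat, items, cols) {
  n <- if (length(cols)) length(cols[[1]]) else 0L
  if (!n) return(out)
  out <- c(out, "loop_", paste0("_", cat, ".", items))
  rows <- do.call(paste, c(lapply(cols, as.character), list(sep = " ")))
  c(out, rows)
}

emit_monomer_block <- function(desc) {
  code <- desc$code
  out <- paste0("data_comp_", code)
  a <- desc$atoms
  out <- emit_loop(out, "chem_comp_atom",
                   c("comp_id", "atom_id", "type_symbol", "type_energy",
                     "partial_charge"),
                   list(rep(code, nrow(a)), cif_quote(a$name),
                        toupper(a$element), cif_quote(a$energy_type),
                        fmt_int(a$charge)))
  b <- desc$bonds
  out <- emit_loop(out, "chem_comp_bond",
                   c("comp_id", "atom_id_1", "atom_id_2", "type", "value_dist",
                     "value_dist_esd"),
                   list(rep(code, nrow(b)), cif_quote(b$atom1),
                        cif_quote(b$atom2), b$order, fmt_len(b$target),
                        fmt_len(b$sigma)))
  an <- desc$angles
  out <- emit_loop(out, "chem_comp_angle",
                   c("comp_id", "atom_id_1", "atom_id_2", "atom_id_3",
                     "value_angle", "value_angle_esd"),
                   list(rep(code, nrow(an)), cif_quote(an$atom1),
                        cif_quote(an$atom2), cif_quote(an$atom3),
                        fmt_deg(an$target), fmt_deg(an$sigma)))
  tr <- desc$torsions
  out <- emit_loop(out, "chem_comp_tor",
                   c("comp_id", "id", "atom_id_1", "atom_id_2", "atom_id_3",
                     "atom_id_4", "value_angle", "value_angle_esd", "period"),
                   list(rep(code, nrow(tr)), cif_quote(tr$id),
                        cif_quote(tr$atom1), cif_quote(tr$atom2),
                        cif_quote(tr$atom3), cif_quote(tr$atom4),
                        fmt_deg(tr$target), fmt_deg(tr$sigma),
                        fmt_int(tr$period)))
  ch <- desc$chirals
  out <- emit_loop(out, "chem_comp_chir",
                   c("comp_id", "id", "atom_id_centre", "atom_id_1",
                     "atom_id_2", "atom_id_3", "volume_sign"),
                   list(rep(code, nrow(ch)), cif_quote(ch$id),
                        cif_quote(ch$centre), cif_quote(ch$atom1),
                        cif_quote(ch$atom2), cif_quote(ch$atom3),
                        sign_to_cif(ch$sign)))
  pl <- desc$planes
  out <- emit_loop(out, "chem_comp_plane_atom",
                   c("comp_id", "plane_id", "atom_id", "dist_esd"),
                   list(rep(code, nrow(pl)), cif_quote(pl$plane_id),
                        cif_quote(pl$atom_id), fmt_len(pl$dist_esd)))
  out <- emit_extra(out, attr(desc, "extra_categories"))
  c(out, "")
}

emit_extra <- function(out, extra) {
  for (cat in names(extra)) {
    df <- extra[[cat]]
    out <- emit_loop(out, cat, names(df), lapply(df, cif_quote))
  }
  out
}

emit_mod_block <- function(mod) {
  id <- mod$id
  out <- paste0("data_mod_", id)
  a <- mod$atoms
  out <- emit_loop(out, "chem_mod_atom",
                   c("mod_id", "function", "atom_id", "new_atom_id",
                     "new_type_symbol", "new_type_energy", "new_charge"),
                   list(rep(id, nrow(a)), a$fun, cif_quote(a$atom_id),
                        cif_quote(a$new_atom_id), cif_quote(a$new_type_symbol),
                        cif_quote(a$new_type_energy), fmt_int(a$new_charge)))
  b <- mod$bonds
  out <- emit_loop(out, "chem_mod_bond",
                   c("mod_id", "function", "atom_id_1", "atom_id_2",
                     "new_type", "new_value_dist", "new_value_dist_esd"),
                   list(rep(id, nrow(b)), b$fun, cif_quote(b$atom1),
                        cif_quote(b$atom2), cif_quote(b$new_order),
                        fmt_len(b$new_target), fmt_len(b$new_sigma)))
  an <- mod$angles
  out <- emit_loop(out, "chem_mod_angle",
                   c("mod_id", "function", "atom_id_1", "atom_id_2",
                     "atom_id_3", "new_value_angle", "new_value_angle_esd"),
                   list(rep(id, nrow(an)), an$fun, cif_quote(an$atom1),
                        cif_quote(an$atom2), cif_quote(an$atom3),
                        fmt_deg(an$new_target), fmt_deg(an$new_sigma)))
  tr <- mod$torsions
  out <- emit_loop(out, "chem_mod_tor",
                   c("mod_id", "function", "id", "atom_id_1", "atom_id_2",
                     "atom_id_3", "atom_id_4", "new_value_angle",
                     "new_value_angle_esd", "new_period"),
                   list(rep(id, nrow(tr)), tr$fun, cif_quote(tr$id),
                        cif_quote(tr$atom1), cif_quote(tr$atom2),
                        cif_quote(tr$atom3), cif_quote(tr$atom4),
                        fmt_deg(tr$new_target), fmt_deg(tr$new_sigma),
                        fmt_int(tr$new_period)))
  ch <- mod$chirals
  out <- emit_loop(out, "chem_mod_chir",
                   c("mod_id", "function", "id", "atom_id_centre", "atom_id_1",
                     "atom_id_2", "atom_id_3", "new_volume_sign"),
                   list(rep(id, nrow(ch)), ch$fun, cif_quote(ch$id),
                        cif_quote(ch$centre), cif_quote(ch$atom1),
                        cif_quote(ch$atom2), cif_quote(ch$atom3),
                        sign_to_cif(ch$new_sign)))
  pl <- mod$planes
  out <- emit_loop(out, "chem_mod_plane_atom",
                   c("mod_id", "function", "plane_id", "atom_id",
                     "new_dist_esd"),
                   list(rep(id, nrow(pl)), pl$fun, cif_quote(pl$plane_id),
                        cif_quote(pl$atom_id), fmt_len(pl$new_dist_esd)))
  c(out, "")
}

emit_link_block <- function(link) {
  id <- link$id
  out <- paste0("data_link_", id)
  b <- link$bonds
  out <- emit_loop(out, "chem_link_bond",
                   c("link_id", "atom_1_comp_id", "atom_id_1",
                     "atom_2_comp_id", "atom_id_2", "type", "value_dist",
                     "value_dist_esd"),
                   list(rep(id, nrow(b)), fmt_int(b$comp1), cif_quote(b$atom1),
                        fmt_int(b$comp2), cif_quote(b$atom2), b$order,
                        fmt_len(b$target), fmt_len(b$sigma)))
  an <- link$angles
  out <- emit_loop(out, "chem_link_angle",
                   c("link_id", "atom_1_comp_id", "atom_id_1",
                     "atom_2_comp_id", "atom_id_2", "atom_3_comp_id",
                     "atom_id_3", "value_angle", "value_angle_esd"),
                   list(rep(id, nrow(an)), fmt_int(an$comp1), cif_quote(an$atom1),
                        fmt_int(an$comp2), cif_quote(an$atom2),
                        fmt_int(an$comp3), cif_quote(an$atom3),
                        fmt_deg(an$target), fmt_deg(an$sigma)))
  tr <- link$torsions
  out <- emit_loop(out, "chem_link_tor",
                   c("link_id", "id", "atom_1_comp_id", "atom_id_1",
                     "atom_2_comp_id", "atom_id_2", "atom_3_comp_id",
                     "atom_id_3", "atom_4_comp_id", "atom_id_4", "value_angle",
                     "value_angle_esd", "period"),
                   list(rep(id, nrow(tr)), cif_quote(tr$id), fmt_int(tr$comp1),
                        cif_quote(tr$atom1), fmt_int(tr$comp2),
                        cif_quote(tr$atom2), fmt_int(tr$comp3),
                        cif_quote(tr$atom3), fmt_int(tr$comp4),
                        cif_quote(tr$atom4), fmt_deg(tr$target),
                        fmt_deg(tr$sigma), fmt_int(tr$period)))
  ch <- link$chirals
  out <- emit_loop(out, "chem_link_chir",
                   c("link_id", "id", "atom_centre_comp_id", "atom_id_centre",
                     "atom_1_comp_id", "atom_id_1", "atom_2_comp_id",
                     "atom_id_2", "atom_3_comp_id", "atom_id_3",
                     "volume_sign"),
                   list(rep(id, nrow(ch)), cif_quote(ch$id),
                        fmt_int(ch$comp_centre), cif_quote(ch$centre),
                        fmt_int(ch$comp1), cif_quote(ch$atom1),
                        fmt_int(ch$comp2), cif_quote(ch$atom2),
                        fmt_int(ch$comp3), cif_quote(ch$atom3),
                        sign_to_cif(ch$sign)))
  pl <- link$planes
  out <- emit_loop(out, "chem_link_plane",
                   c("link_id", "plane_id", "atom_comp_id", "atom_id",
                     "dist_esd"),
                   list(rep(id, nrow(pl)), cif_quote(pl$plane_id),
                        fmt_int(pl$comp), cif_quote(pl$atom_id),
                        fmt_len(pl$dist_esd)))
  c(out, "")
}

emit_comp_list <- function(monomers) {
  out <- "data_comp_list"
  n <- length(monomers)
  if (n) {
    nh <- vapply(monomers, function(m) sum(m$atoms$element != "H"), integer(1))
    out <- emit_loop(out, "chem_comp",
                     c("id", "three_letter_code", "name", "group",
                       "number_atoms_all", "number_atoms_nh", "desc_level"),
                     list(names(monomers), names(monomers),
                          cif_quote(vapply(monomers, function(m)
                            if (nzchar(m$name)) m$name else NA_character_, character(1))),
                          vapply(monomers, `[[`, character(1), "group"),
                          fmt_int(vapply(monomers, function(m) nrow(m$atoms), integer(1))),
                          fmt_int(nh),
                          vapply(monomers, function(m)
                            if (m$level == "minimal") "M" else ".", character(1))))
  }
  c(out, "")
}

emit_mod_list <- function(mods) {
  out <- "data_mod_list"
  if (length(mods)) {
    out <- emit_loop(out, "chem_mod", c("id", "name", "comp_id", "group_id"),
                     list(names(mods),
                          cif_quote(vapply(mods, function(m)
                            if (nzchar(m$name)) m$name else NA_character_, character(1))),
                          cif_quote(vapply(mods, `[[`, character(1), "parent")),
                          cif_quote(vapply(mods, `[[`, character(1), "group"))))
  }
  c(out, "")
}

emit_link_list <- function(links) {
  out <- "data_link_list"
  if (length(links)) {
    g <- function(f) cif_quote(vapply(links, function(l) {
      v <- l[[f]]
      if (is.null(v) || is.na(v) || !nzchar(v)) NA_character_ else v
    }, character(1)))
    out <- emit_loop(out, "chem_link",
                     c("id", "comp_id_1", "mod_id_1", "group_comp_1",
                       "comp_id_2", "mod_id_2", "group_comp_2", "name"),
                     list(names(links), g("comp1"), g("mod1"), g("group1"),
                          g("comp2"), g("mod2"), g("group2"), g("name")))
  }
  c(out, "")
}

#' Write a restraint library as CIF
#'
#' Deterministic serialization: index blocks first (comp list, mod list,
#' link list - each written only when the corresponding entries exist, or
#' all three for a completely empty library), then entry blocks in
#' insertion order, then any opaque blocks carried through from
#' [read_library()].  Distances are printed with 3 decimals, angles with 2.
#' The output is re-readable, and writing the re-read library reproduces
#' the document byte for byte.
#'
#' @param lib A [restraint_library()].
#' @param path Optional file to write.
#' @param lists Which index blocks to force; default "auto" as above.
#' @return The document as a single string (invisibly when `path` given).
#' @export
write_library <- function(lib, path = NULL,
                          lists = c("auto", "mod_link", "all")) {
  lists <- match.arg(lists)
  # refuse to serialize an entry whose internal references dangle
  for (m in lib$monomers) {
    rep <- validate_monomer(m)
    bad <- rep[rep$class %in% c("dangling_reference", "duplicate_atom"), ]
    if (nrow(bad))
      stop("cannot serialize monomer '", m$code, "': ", bad$message[1])
  }
  out <- character(0)
  empty <- !length(lib$monomers) && !length(lib$modifications) && !length(lib$links)
  want_comp <- (lists == "all") || (lists == "auto" && (length(lib$monomers) > 0L || empty))
  want_mod <- lists != "auto" || length(lib$modifications) > 0L || empty
  want_link <- lists != "auto" || length(lib$links) > 0L || empty
  if (want_comp) out <- c(out, emit_comp_list(lib$monomers))
  if (want_mod) out <- c(out, emit_mod_list(lib$modifications))
  if (want_link) out <- c(out, emit_link_list(lib$links))
  for (m in lib$monomers) out <- c(out, emit_monomer_block(m))
  for (m in lib$modifications) out <- c(out, emit_mod_block(m))
  for (l in lib$links) out <- c(out, emit_link_block(l))
  for (nm in names(lib$opaque)) {
    out <- c(out, paste0("data_", nm))
    out <- emit_extra(out, lib$opaque[[nm]])
    out <- c(out, "")
  }
  doc <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(doc))
  }
  doc
}
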