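.lc_cache <- new.env(parent = emptyenv())

#' Lipid class ontology
#'
#' The class/category mapping used throughout the package, shipped as a
#' plain tab-delimited resource (`extdata/lipid_classes.tsv`) so it can be
#' inspected or extended. Each row gives a shorthand class token (e.g. `PC`,
#' `Cer`, `PC O-`), the lipid category it belongs to, the number of
#' carbon chains a species of that class carries (its arity), and whether
#' the class is an ether lipid.
#'
#' Categories follow the standard grouping: cholesteryl esters are sterols;
#' ceramides, hexosylceramides and sphingomyelins are sphingolipids; di- and
#' triacylglycerols are glycerolipids; the diacyl phospholipids (and
#' cardiolipin and the ether PC/PE) are glycerophospholipids; and the
#' lyso-phospholipids are glycerophospholipid intermediates.
#'
#' @param path Optional path to an alternative mapping file with the same
#'   columns (`lipid_class`, `category`, `n_chains`, `ether`).
#' @return A data.frame with columns `lipid_class`, `category`, `n_chains`,
#'   `ether`.
#' @export
#' @examples
#' head(lipid_classes())
lipid_classes <- function(path = NULL) {
  if (!is.null(path)) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    validate_class_table(tab)
    return(tab)
  }
  if (is.null(.lc_cache$classes)) {
    default <- system.file("extdata", "lipid_classes.tsv",
                           package = "lipidcontrast", mustWork = TRUE)
    tab <- utils::read.delim(default, stringsAsFactors = FALSE, check.names = FALSE)
    validate_class_table(tab)
    .lc_cache$classes <- tab
  }
  .lc_cache$classes
}

validate_class_table <- function(tab) {
  need <- c("lipid_class", "category", "n_chains", "ether")
  if (!all(need %in% names(tab))) {
    abort("validation_error", sprintf(
      "class mapping must have columns %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(tab$lipid_class)) {
    abort("validation_error", "duplicated lipid_class in class mapping")
  }
  invisible(tab)
}

lipid_categories <- function() {
  unique(lipid_classes()$category)
}

#' Lipid category of a class
#'
#' Total function mapping every shorthand class token to one of the five
#' lipid categories (sterols, sphingolipids, glycerolipids,
#' glycerophospholipids, glycerophospholipid intermediates). Ether classes
#' (`PC O-`, `LPE O-`, ...) inherit the category of their diacyl parent.
#'
#' @param lipid_class Character vector of class tokens.
#' @return Character vector of categories, same length.
#' @export
#' @examples
#' category_of(c("Cer", "LPC", "TAG"))
category_of <- function(lipid_class) {
  tab <- lipid_classes()
  idx <- match(lipid_class, tab$lipid_class)
  if (anyNA(idx)) {
    bad <- unique(lipid_class[is.na(idx)])
    abort("nomenclature_error",
          sprintf("unknown lipid class token: %s", paste(bad, collapse = ", ")),
          token = bad)
  }
  tab$category[idx]
}

chain_regex <- "^\\s*([0-9]+)\\s*:\\s*([0-9]+)\\s*(?:;\\s*([0-9]+))?\\s*$"

#' Parse a lipid shorthand name
#'
#' Parses Lipotype-style species shorthand: a class token, an optional `O-`
#' ether marker, then one or more `carbons:double_bonds` chain tokens
#' (optionally suffixed `;hydroxylations`) separated by `/`. Both the
#' compact dialect (`"Cer 18:1;2/17:0"`) and the spaced typesetting dialect
#' (`"ceramide 18 : 1;2/17 : 0"` style spacing, i.e. `"Cer 18 : 1;2/17 : 0"`)
#' are accepted; [canonical_name()] renders the compact form.
#'
#' @param name A single species name.
#' @return An object of class `lipid_species`: a list with `raw_name`,
#'   `lipid_class`, `category`, `chains` (data.frame of `carbons`,
#'   `double_bonds`, `hydroxylations`), and `ether`.
#' @export
#' @examples
#' sp <- parse_species("PC 17:0/17:0")
#' sp$category
#' parse_species("CL 16:1/15:0/15:0/15:0")$chains
parse_species <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name)) {
    abort("syntax_error", "species name must be a single character string")
  }
  m <- regmatches(name, regexec("^\\s*([A-Za-z]+)\\s*(O-)?\\s*(.*?)\\s*$", name))[[1]]
  if (length(m) == 0L || !nzchar(m[2])) {
    abort("syntax_error", sprintf("malformed species name: '%s'", name))
  }
  token <- m[2]
  ether <- nzchar(m[3])
  cls <- if (ether) paste(token, "O-") else token
  tab <- lipid_classes()
  row <- match(cls, tab$lipid_class)
  if (is.na(row)) {
    abort("nomenclature_error",
          sprintf("unknown lipid class token: '%s'", cls), token = cls)
  }
  rest <- m[4]
  if (!nzchar(rest)) {
    abort("syntax_error", sprintf("no chain tokens in '%s'", name))
  }
  parts <- strsplit(rest, "/", fixed = TRUE)[[1]]
  chains <- lapply(parts, function(p) {
    cm <- regmatches(p, regexec(chain_regex, p))[[1]]
    if (length(cm) == 0L) {
      abort("syntax_error",
            sprintf("malformed chain token '%s' in '%s'", trimws(p), name))
    }
    c(carbons = as.integer(cm[2]),
      double_bonds = as.integer(cm[3]),
      hydroxylations = if (nzchar(cm[4])) as.integer(cm[4]) else 0L)
  })
  chains <- as.data.frame(do.call(rbind, chains))
  if (any(chains$carbons < 1L)) {
    abort("syntax_error", sprintf("chain with zero carbons in '%s'", name))
  }
  arity <- tab$n_chains[row]
  if (nrow(chains) != arity) {
    abort("arity_error", sprintf(
      "class %s requires %d chain(s), got %d in '%s'",
      cls, arity, nrow(chains), name))
  }
  structure(
    list(raw_name = name, lipid_class = cls, category = tab$category[row],
         chains = chains, ether = tab$ether[row]),
    class = "lipid_species"
  )
}

#' Canonical rendering of a lipid species
#'
#' Deterministic, whitespace-normalized rendering such that
#' `parse_species(canonical_name(s))` reproduces `s` exactly (the
#' hydroxylation suffix is omitted when zero).
#'
#' @param species A `lipid_species` object, or a character name which is
#'   parsed first.
#' @return A single character string.
#' @export
#' @examples
#' canonical_name("PC  17:0 / 17:0")
canonical_name <- function(species) {
  if (is.character(species)) species <- parse_species(species)
  stopifnot(inherits(species, "lipid_species"))
  ch <- species$chains
  tok <- paste0(ch$carbons, ":", ch$double_bonds,
                ifelse(ch$hydroxylations > 0, paste0(";", ch$hydroxylations), ""))
  paste(species$lipid_class, paste(tok, collapse = "/"))
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(sprintf("<lipid_species> %s [%s, %s]\n",
              canonical_name(x), x$lipid_class, x$category))
  invisible(x)
}

#' @export
format.lipid_species <- function(x, ...) canonical_name(x)

#' Annotate a vector of species names
#'
#' Vectorized wrapper around [parse_species()] producing one annotation row
#' per name. Parse failures are re-signalled with the offending row index.
#'
#' @param names Character vector of shorthand names.
#' @return data.frame with columns `name`, `canonical`, `lipid_class`,
#'   `category`, `n_chains`, `total_carbons`, `total_double_bonds`,
#'   `total_hydroxylations`, `ether`.
#' @export
annotate_lipids <- function(names) {
  if (length(names) == 0L) {
    return(data.frame(name = character(), canonical = character(),
                      lipid_class = character(), category = character(),
                      n_chains = integer(), total_carbons = integer(),
                      total_double_bonds = integer(),
                      total_hydroxylations = integer(), ether = logical(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(names), function(i) {
    sp <- withCallingHandlers(
      tryCatch(parse_species(names[i]), lipidcontrast_error = function(e) {
        abort(class(e)[1], sprintf("row %d: %s", i, conditionMessage(e)), row = i)
      })
    )
    data.frame(
      name = names[i],
      canonical = canonical_name(sp),
      lipid_class = sp$lipid_class,
      category = sp$category,
      n_chains = nrow(sp$chains),
      total_carbons = sum(sp$chains$carbons),
      total_double_bonds = sum(sp$chains$double_bonds),
      total_hydroxylations = sum(sp$chains$hydroxylations),
      ether = sp$ether,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
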