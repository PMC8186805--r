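#' Tissue label dictionary
#'
#' The segmented head models used throughout the package carry one small
#' integer tissue code per voxel.  Code 0 is reserved for air/background;
#' every non-air code that appears in a volume must be present in the
#' media table used to simulate it.
#'
#' @return A data frame with columns `code` and `name`.
#' @export
tissue_labels <- function() {
  data.frame(
    code = 0:10,
    name = c("air", "skin", "muscle", "skull", "dura", "CSF",
             "GM", "WM", "NMA", "eyes", "nasal_cavity"),
    stringsAsFactors = FALSE
  )
}

tissue_code <- function(name) {
  tl <- tissue_labels()
  i <- match(name, tl$name)
  if (anyNA(i)) stop("unknown tissue name(s): ", paste(name[is.na(i)], collapse = ", "))
  tl$code[i]
}

tissue_name <- function(code) {
  tl <- tissue_labels()
  i <- match(code, tl$code)
  if (anyNA(i)) stop("unknown tissue code(s): ", paste(code[is.na(i)], collapse = ", "))
  tl$name[i]
}

#' Default optical property table at 690 nm
#'
#' Per-tissue absorption coefficient `mu_a` (mm^-1), scattering coefficient
#' `mu_s` (mm^-1), scattering anisotropy `g` and refractive index `n` for
#' the ten supported head tissue types, at a wavelength of 690 nm.  All
#' tissues share n = 1.37; eyes mimic CSF (water-like, very low scattering)
#' and non-myelinated axons (NMA) mimic white matter.  Air is
#' non-interacting (`mu_a = mu_s = 0`, n = 1) and photons traverse it
#' ballistically.
#'
#' @return An object of class `media_table`: a data frame with columns
#'   `code`, `name`, `mu_a`, `mu_s`, `g`, `n`, plus attributes
#'   `wavelength_nm` and `n_out` (ambient refractive index, 1.0).
#' @export
default_media_table <- function() {
  tab <- data.frame(
    name = c("air", "skin", "muscle", "skull", "dura", "CSF",
             "GM", "WM", "NMA", "eyes", "nasal_cavity"),
    mu_a = c(0, 0.0101, 0.0101, 0.0101, 0.0101, 0.0004,
             0.02, 0.07, 0.07, 0.0004, 0.0101),
    mu_s = c(0, 80, 80, 100, 80, 1,
             8.4, 40.1, 40.1, 1, 80),
    g    = c(0, 0.99, 0.99, 0.99, 0.99, 0.99,
             0.90, 0.85, 0.85, 0.99, 0.99),
    n    = c(1, 1.37, 1.37, 1.37, 1.37, 1.37,
             1.37, 1.37, 1.37, 1.37, 1.37),
    stringsAsFactors = FALSE
  )
  tab$code <- tissue_code(tab$name)
  tab <- tab[, c("code", "name", "mu_a", "mu_s", "g", "n")]
  structure(tab, class = c("media_table", "data.frame"),
            wavelength_nm = 690, n_out = 1.0)
}

#' Look up the optical properties of one tissue
#'
#' @param table a `media_table`.
#' @param label tissue code (integer) or tissue name (character).
#' @return A one-row data frame with `mu_a`, `mu_s`, `g`, `n`.
#' @export
media_lookup <- function(table, label) {
  stopifnot(inherits(table, "media_table"))
  if (is.character(label)) {
    i <- match(label, table$name)
  } else {
    i <- match(as.integer(label), table$code)
  }
  if (anyNA(i)) stop("tissue not present in media table: ", paste(label[is.na(i)], collapse = ", "))
  table[i, c("mu_a", "mu_s", "g", "n"), drop = FALSE]
}

#' Reduced scattering coefficient
#'
#' `mu_s' = mu_s * (1 - g)`, the similarity-invariant scattering scale that
#' governs diffuse transport.
#'
#' @param table a `media_table`.
#' @return Named numeric vector of mu_s' (mm^-1) per tissue.
#' @export
reduced_scattering <- function(table) {
  stopifnot(inherits(table, "media_table"))
  stats::setNames(table$mu_s * (1 - table$g), table$name)
}

#' Similarity-scaled media table
#'
#' Replaces each tissue's (mu_s, g) by (mu_s(1-g), 0).  The similarity
#' relations of transport theory leave diffuse light fields essentially
#' unchanged under this substitution while lengthening the mean scattering
#' step by 1/(1-g); for the highly forward-scattering extracerebral
#' tissues (g = 0.99) this accelerates a CPU Monte Carlo run by roughly
#' two orders of magnitude.  Intended for desk-scale experiments; the
#' unscaled table remains the reference for physics validation.
#'
#' @param table a `media_table`.
#' @return A `media_table` with scaled properties and attribute
#'   `similarity_scaled = TRUE`.
#' @export
similarity_scale <- function(table) {
  stopifnot(inherits(table, "media_table"))
  tissue <- table$code != 0L
  table$mu_s[tissue] <- table$mu_s[tissue] * (1 - table$g[tissue])
  table$g[tissue] <- 0
  attr(table, "similarity_scaled") <- TRUE
  table
}

#' Read a media table override from CSV or YAML
#'
#' The file replaces values for the tissues it names; unnamed tissues keep
#' the shipped defaults.  CSV columns (or YAML keys per tissue entry):
#' `tissue, mu_a, mu_s, g, n`.
#'
#' @param path file path (`.csv`, `.yaml` or `.yml`).
#' @param base table to override; defaults to [default_media_table()].
#' @return A `media_table`.
#' @export
read_media_table <- function(path, base = default_media_table()) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    ov <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    y <- yaml::read_yaml(path)
    ov <- do.call(rbind, lapply(names(y), function(nm) {
      e <- y[[nm]]
      # YAML 1.1 parses a bare key "n" as boolean FALSE; restore it
      names(e)[names(e) %in% c("FALSE", "false")] <- "n"
      if (is.null(e$n)) stop("media entry '", nm, "' lacks a refractive index")
      data.frame(tissue = nm, mu_a = e$mu_a, mu_s = e$mu_s,
                 g = e$g, n = e$n, stringsAsFactors = FALSE)
    }))
  } else stop("unsupported media table format: .", ext)
  need <- c("tissue", "mu_a", "mu_s", "g", "n")
  if (!all(need %in% names(ov))) {
    stop("media override must provide columns: ", paste(need, collapse = ", "))
  }
  i <- match(ov$tissue, base$name)
  if (anyNA(i)) stop("unknown tissue in media override: ",
                     paste(ov$tissue[is.na(i)], collapse = ", "))
  for (col in c("mu_a", "mu_s", "g", "n")) base[[col]][i] <- ov[[col]]
  validate_media_table(base)
  base
}

validate_media_table <- function(table) {
  stopifnot(inherits(table, "media_table"))
  if (any(table$mu_a < 0)) stop("mu_a must be non-negative")
  if (any(table$mu_s < 0)) stop("mu_s must be non-negative")
  if (any(abs(table$g) >= 1 & table$code != 0L)) stop("|g| must be < 1 for tissue")
  if (any(table$n <= 0)) stop("refractive index must be positive")
  invisible(table)
}

#' @export
print.media_table <- function(x, ...) {
  cat(sprintf("Media table (%d tissues, %g nm, ambient n = %g%s)\n",
              nrow(x), attr(x, "wavelength_nm"), attr(x, "n_out"),
              if (isTRUE(attr(x, "similarity_scaled"))) ", similarity-scaled" else ""))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
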