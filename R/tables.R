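#' Element tables shipped with the package
#'
#' Three editable lookup tables drive structure preparation: van der Waals
#' radii (Alvarez compilation) used to define the occupied envelope of each
#' atom, covalent radii (Cordero compilation) used only to detect X-H bonds,
#' and target neutron-derived X-H distances used to correct the systematic
#' foreshortening of hydrogen positions in X-ray structures.
#'
#' Each loader reads the packaged CSV by default; pass `path` to substitute a
#' user-edited table with the same columns.
#'
#' @param path Optional path to a replacement CSV.
#' @return A tibble: `vdw_radii()` has columns `element`, `r_vdw` (angstrom);
#'   `covalent_radii()` has `element`, `r_cov`; `xh_distances()` has
#'   `element`, `d_xh` (the heavy-atom element and the normalized X-H bond
#'   length).
#' @export
vdw_radii <- function(path = NULL) {
  read_element_table(path %||% pkg_file("vdw_radii_alvarez.csv"), "r_vdw")
}

#' @rdname vdw_radii
#' @export
covalent_radii <- function(path = NULL) {
  read_element_table(path %||% pkg_file("covalent_radii.csv"), "r_cov")
}

#' @rdname vdw_radii
#' @export
xh_distances <- function(path = NULL) {
  read_element_table(path %||% pkg_file("xh_neutron_distances.csv"), "d_xh")
}

pkg_file <- function(name) {
  p <- system.file("extdata", name, package = "voidpart")
  if (!nzchar(p)) abort(paste0("packaged table not found: ", name))
  p
}

read_element_table <- function(path, value_col) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("element", value_col) %in% names(df))) {
    abort(paste0("table ", path, " must have columns 'element' and '", value_col, "'"))
  }
  if (any(df[[value_col]] <= 0)) abort("table radii/distances must be positive")
  df
}

# named-vector lookup helper
table_lookup <- function(tbl, value_col) {
  setNames(tbl[[value_col]], tbl$element)
}
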