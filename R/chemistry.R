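#' Built-in registry of the four NIMS-tagged lignin model dimers
#'
#' Each substrate is a lignin dimer carrying a perfluorinated NIMS tag,
#' observed as its protonated ion \eqn{[M+H]^+}. The registry records the
#' nominal substrate ion m/z and a catalog of named product mass offsets
#' (oxidations, cleavage fragments, coupling products) observed for each
#' interunit bond type.
#'
#' Nominal (integer) mass arithmetic is the default because reported product
#' ions are integer m/z; `offset_mode = "monoisotopic"` switches the common
#' small shifts (+16, +32, -2, -16) to their exact monoisotopic values for
#' high-resolution data.
#'
#' The beta-O-4' substrate ion m/z is not hard-coded: it must be supplied by
#' the user (e.g. read off the measured spectrum of the substrate batch).
#' When omitted, the substrate is returned with `ion_mz = NA` and any
#' arithmetic on it errors.
#'
#' @param b_O_4_mz protonated-ion m/z of the beta-O-4' substrate, or `NULL`.
#' @param offset_mode `"nominal"` (integer offsets, default) or
#'   `"monoisotopic"`.
#' @return A named list of `lig_substrate` objects with fields `name`,
#'   `ion_mz` and `products` (data frame of `label`, `offset`,
#'   `expected_category`).
#' @examples
#' reg <- lig_substrates()
#' reg[["5-5"]]$ion_mz            # 962
#' expected_product_mz(reg[["5-5"]], 16)   # 978, the [M+16] oxidation
#' @export
lig_substrates <- function(b_O_4_mz = NULL, offset_mode = c("nominal", "monoisotopic")) {
  offset_mode <- match.arg(offset_mode)
  prod <- function(label, offset, category) {
    data.frame(label = label, offset = offset, expected_category = category,
               stringsAsFactors = FALSE)
  }
  mono <- c("16" = 15.9949, "32" = 31.9898, "-2" = -2.0157, "-16" = -15.9949)
  adj <- function(p) {
    if (offset_mode == "monoisotopic") {
      key <- as.character(p$offset)
      hit <- key %in% names(mono)
      p$offset[hit] <- unname(mono[key[hit]])
    }
    p
  }
  bb <- rbind(
    prod("M+16 oxidation",                 16, "modified"),
    prod("M+32 oxidation",                 32, "modified"),
    prod("hydrolyzed acid product (998)", -90, "cleaved"),
    prod("lactone product (980)",        -108, "cleaved"),
    prod("oxidized cleavage product (982)", -106, "cleaved"),
    prod("minor cleavage (898)",         -190, "cleaved"),
    prod("substrate dimer (2173)",       1085, "polymerized"))
  s55 <- rbind(
    prod("M+16 oxidation", 16, "modified"),
    prod("M+32 oxidation", 32, "modified"),
    prod("primary-alcohol oxidation", -2, "modified"))
  s4O5 <- rbind(
    prod("M+16 oxidation", 16, "modified"),
    prod("M+32 oxidation", 32, "modified"),
    prod("primary-alcohol oxidation", -2, "modified"),
    prod("oxygen loss", -16, "modified"))
  bO4 <- rbind(
    prod("M+16 oxidation", 16, "modified"),
    prod("M+32 oxidation", 32, "modified"))
  defs <- list(
    new_substrate("b-O-4", b_O_4_mz %||% NA_real_, adj(bO4)),
    new_substrate("b-b",   1088, adj(bb)),
    new_substrate("5-5",    962, adj(s55)),
    new_substrate("4-O-5",  978, adj(s4O5)))
  names(defs) <- vapply(defs, `[[`, "", "name")
  defs
}

#' Construct a substrate definition
#'
#' @param name bond-type label, one of `"b-O-4"`, `"b-b"`, `"5-5"`, `"4-O-5"`.
#' @param ion_mz protonated-ion m/z (may be `NA` for a substrate whose mass
#'   has not been supplied yet).
#' @param products data frame with columns `label`, `offset`,
#'   `expected_category`.
#' @param mz_range acquisition range the ion must fall into.
#' @return A `lig_substrate` object.
#' @export
new_substrate <- function(name, ion_mz, products,
                          mz_range = c(200, 3500)) {
  stopifnot(name %in% c("b-O-4", "b-b", "5-5", "4-O-5"))
  if (!is.na(ion_mz)) {
    if (ion_mz <= 0 || ion_mz < mz_range[1] || ion_mz > mz_range[2])
      stop("substrate ion m/z must lie in the acquisition range [",
           mz_range[1], ", ", mz_range[2], "]")
  }
  stopifnot(all(c("label", "offset", "expected_category") %in% names(products)))
  if (anyDuplicated(products$offset) || any(!is.finite(products$offset)))
    stop("product offsets must be finite and distinct")
  stopifnot(all(products$expected_category %in%
                  c("unreacted", "modified", "cleaved", "polymerized")))
  structure(list(name = name, ion_mz = ion_mz, products = products),
            class = "lig_substrate")
}

#' @export
print.lig_substrate <- function(x, ...) {
  cat(sprintf("<lig_substrate> %s  [M+H]+ m/z %s  (%d products)\n",
              x$name, format(x$ion_mz), nrow(x$products)))
  invisible(x)
}

check_ion_mz <- function(substrate) {
  if (is.na(substrate$ion_mz))
    stop("ion m/z for substrate '", substrate$name,
         "' has not been supplied; pass it to lig_substrates() or the registry config")
  substrate$ion_mz
}

#' Expected product m/z for a mass offset
#'
#' @param substrate a `lig_substrate`.
#' @param offset signed mass offset in Da.
#' @return `substrate$ion_mz + offset`.
#' @examples
#' expected_product_mz(lig_substrates()[["4-O-5"]], 32)  # 1010
#' @export
expected_product_mz <- function(substrate, offset) {
  check_ion_mz(substrate) + offset
}

#' Annotate an observed m/z against a substrate's product catalog
#'
#' Returns the registered product whose expected m/z lies within `tol` of the
#' observation. If several products tie, the one with the smaller absolute
#' offset wins.
#'
#' @param mz observed m/z.
#' @param substrate a `lig_substrate`.
#' @param tol matching tolerance in Da (default 0.1, the binning tolerance).
#' @return One row of the product table (plus an `mz_expected` column), or
#'   `NULL` when nothing matches.
#' @examples
#' annotate_peak(1104, lig_substrates()[["b-b"]])  # M+16 oxidation
#' @export
annotate_peak <- function(mz, substrate, tol = 0.1) {
  stopifnot(tol > 0)
  S <- check_ion_mz(substrate)
  exp_mz <- S + substrate$products$offset
  d <- abs(mz - exp_mz)
  hit <- which(d <= tol)
  if (!length(hit)) return(NULL)
  hit <- hit[order(abs(substrate$products$offset[hit]))][1]
  out <- substrate$products[hit, , drop = FALSE]
  out$mz_expected <- exp_mz[hit]
  rownames(out) <- NULL
  out
}

#' Write / read a substrate registry as a YAML config
#'
#' The on-disk form is a list of records with keys `name`, `ion_mz` and
#' `products` (each with `label`, `offset`, `expected_category`), so a
#' registry can be versioned alongside an experiment or edited for new
#' substrate batches.
#'
#' @param registry named list of `lig_substrate` objects.
#' @param path file path.
#' @return `read_substrate_registry` returns the registry list.
#' @export
write_substrate_registry <- function(registry, path) {
  recs <- lapply(unname(registry), function(s) {
    list(name = s$name, ion_mz = if (is.na(s$ion_mz)) NULL else s$ion_mz,
         products = lapply(seq_len(nrow(s$products)), function(i)
           as.list(s$products[i, c("label", "offset", "expected_category")])))
  })
  yaml::write_yaml(recs, path)
  invisible(path)
}

#' @rdname write_substrate_registry
#' @export
read_substrate_registry <- function(path) {
  recs <- yaml::read_yaml(path)
  defs <- lapply(recs, function(r) {
    products <- do.call(rbind, lapply(r$products, function(p)
      data.frame(label = p$label, offset = as.numeric(p$offset),
                 expected_category = p$expected_category,
                 stringsAsFactors = FALSE)))
    new_substrate(r$name, r$ion_mz %||% NA_real_, products)
  })
  names(defs) <- vapply(defs, `[[`, "", "name")
  defs
}
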