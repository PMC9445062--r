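#' Biomarker panel construction and validation
#'
#' A biomarker panel records, for every analyte in an NMR-metabolomics style
#' panel, its name, biological class, whether it is directly measured or a
#' derived ratio, and for ratios the measured numerator and denominator.
#' The default panel mirrors the structure of a targeted lipoprotein /
#' metabolite platform: 146 measured biomarkers plus 79 derived ratios,
#' 225 in total.
#'
#' @param spec a data.frame with columns `name`, `class`, `is_ratio`,
#'   `numerator`, `denominator`. For measured markers `numerator` and
#'   `denominator` are `NA`; for ratios they must name measured markers
#'   present in `spec`.
#' @return An object of class `biomarker_panel`: the validated spec with
#'   attributes `n_measured` and `n_ratio`.
#' @examples
#' p <- default_panel()
#' sum(!p$is_ratio)  # 146 measured
#' sum(p$is_ratio)   # 79 ratios
#' @export
build_panel <- function(spec) {
  stopifnot(is.data.frame(spec))
  required <- c("name", "class", "is_ratio")
  missing_cols <- setdiff(required, names(spec))
  if (length(missing_cols))
    stop("panel spec lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!"numerator" %in% names(spec)) spec$numerator <- NA_character_
  if (!"denominator" %in% names(spec)) spec$denominator <- NA_character_
  spec$name <- as.character(spec$name)
  spec$class <- as.character(spec$class)
  spec$is_ratio <- as.logical(spec$is_ratio)
  spec$numerator <- as.character(spec$numerator)
  spec$denominator <- as.character(spec$denominator)

  if (anyDuplicated(spec$name))
    stop("duplicate biomarker names in panel spec: ",
         paste(unique(spec$name[duplicated(spec$name)]), collapse = ", "))
  bad_class <- setdiff(spec$class, panel_classes())
  if (length(bad_class))
    stop("unknown biomarker class: ", paste(bad_class, collapse = ", "))

  measured <- spec$name[!spec$is_ratio]
  ratios <- spec[spec$is_ratio, , drop = FALSE]
  if (nrow(ratios)) {
    refs <- c(ratios$numerator, ratios$denominator)
    if (anyNA(refs))
      stop("ratio rows must name a numerator and a denominator")
    unknown <- setdiff(refs, measured)
    if (length(unknown))
      stop("ratio definition references unknown measured marker(s): ",
           paste(unique(unknown), collapse = ", "))
  }
  rownames(spec) <- NULL
  structure(spec,
            n_measured = length(measured),
            n_ratio = nrow(ratios),
            class = c("biomarker_panel", "data.frame"))
}

#' Recognised biomarker classes
#' @return Character vector of the class labels a panel may use.
#' @export
panel_classes <- function() {
  c("lipoprotein_lipid", "lipoprotein_subclass", "particle_size",
    "apolipoprotein", "fatty_acid", "amino_acid", "glycolysis",
    "ketone_body", "fluid_balance", "inflammation")
}

#' Names of the measured (non-ratio) markers of a panel
#' @param panel a `biomarker_panel`
#' @export
measured_markers <- function(panel) panel$name[!panel$is_ratio]

#' Names of all markers of a panel, in panel order
#' @param panel a `biomarker_panel`
#' @export
panel_markers <- function(panel) panel$name

#' Default 225-biomarker panel
#'
#' A structurally faithful stand-in for a targeted NMR metabolomics panel:
#' 14 lipoprotein subclasses (six VLDL, IDL, three LDL, four HDL) with eight
#' measured lipid quantities each, three mean particle diameters, two
#' apolipoproteins, eight fatty acid measures, nine amino acids, five
#' glycolysis-related metabolites, four ketone bodies, two fluid-balance
#' markers and one inflammation marker (146 measured), plus 79 derived
#' ratios (relative lipid compositions within subclasses, fatty-acid
#' fractions of total fatty acids, and two apolipoprotein/lipid ratios).
#' Marker names are synthetic; real panels are supplied via [build_panel()]
#' or [read_panel_spec()].
#'
#' @return a `biomarker_panel` with 146 measured + 79 ratio markers.
#' @export
default_panel <- function() {
  sub <- c("XXL_VLDL", "XL_VLDL", "L_VLDL", "M_VLDL", "S_VLDL", "XS_VLDL",
           "IDL", "L_LDL", "M_LDL", "S_LDL",
           "XL_HDL", "L_HDL", "M_HDL", "S_HDL")
  lipid_measures <- c("P", "L", "PL", "C", "CE", "FC", "TG")
  rows <- list()
  add <- function(name, class, is_ratio = FALSE, num = NA, den = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, class = class, is_ratio = is_ratio,
      numerator = num, denominator = den, stringsAsFactors = FALSE)
  }
  # 14 x 8 = 112 subclass measures: particle concentration, total lipids,
  # phospholipids, total/esterified/free cholesterol, triglycerides, and
  # average particle diameter per subclass
  for (s in sub) {
    for (m in lipid_measures) add(paste(s, m, sep = "_"), "lipoprotein_subclass")
    add(paste(s, "D", sep = "_"), "lipoprotein_subclass")
  }
  # 3 class-average particle sizes
  for (s in c("VLDL_size", "LDL_size", "HDL_size")) add(s, "particle_size")
  # 2 apolipoproteins
  add("ApoA1", "apolipoprotein"); add("ApoB", "apolipoprotein")
  # 8 fatty acids
  fa <- c("TotFA", "DHA", "LA", "FAw3", "FAw6", "PUFA", "MUFA", "SFA")
  for (f in fa) add(f, "fatty_acid")
  # 9 amino acids
  for (a in c("Ala", "Gln", "Gly", "His", "Ile", "Leu", "Val", "Phe", "Tyr"))
    add(a, "amino_acid")
  # 5 glycolysis-related
  for (g in c("Glucose", "Lactate", "Pyruvate", "Citrate", "Glycerol"))
    add(g, "glycolysis")
  # 4 ketone bodies
  for (k in c("bOHbutyrate", "Acetoacetate", "Acetate", "Acetone"))
    add(k, "ketone_body")
  # 2 fluid balance, 1 inflammation
  add("Creatinine", "fluid_balance"); add("Albumin", "fluid_balance")
  add("GlycA", "inflammation")

  # 79 ratios: 5 relative lipid contents per subclass (70), 7 fatty-acid
  # fractions, ApoB/ApoA1, TG/PL in IDL
  for (s in sub) {
    for (m in c("PL", "C", "CE", "FC", "TG")) {
      add(paste(s, m, "pct", sep = "_"), "lipoprotein_lipid", TRUE,
          paste(s, m, sep = "_"), paste(s, "L", sep = "_"))
    }
  }
  for (f in setdiff(fa, "TotFA"))
    add(paste0(f, "_pct"), "fatty_acid", TRUE, f, "TotFA")
  add("ApoB_by_ApoA1", "apolipoprotein", TRUE, "ApoB", "ApoA1")
  add("IDL_TG_by_PL", "lipoprotein_lipid", TRUE, "IDL_TG", "IDL_PL")

  build_panel(do.call(rbind, rows))
}

#' Compute derived ratio columns of a panel
#'
#' Given a matrix (or data.frame) of measured biomarker concentrations,
#' appends the panel's derived ratios (numerator / denominator, elementwise).
#' Cells whose denominator is zero or negative are set to `NA` and counted;
#' measured columns pass through unchanged.
#'
#' @param measured matrix or data.frame whose columns include all measured
#'   markers of `panel`.
#' @param panel a `biomarker_panel`.
#' @return matrix with one column per panel marker, in panel order, with an
#'   attribute `n_invalid_denominator` giving the number of flagged cells.
#' @export
compute_ratios <- function(measured, panel) {
  measured <- as.matrix(measured)
  meas_names <- measured_markers(panel)
  missing <- setdiff(meas_names, colnames(measured))
  if (length(missing))
    stop("measured matrix lacks marker column(s): ",
         paste(missing, collapse = ", "))
  out <- matrix(NA_real_, nrow(measured), nrow(panel),
                dimnames = list(rownames(measured), panel$name))
  out[, meas_names] <- measured[, meas_names]
  n_bad <- 0L
  ratios <- panel[panel$is_ratio, , drop = FALSE]
  for (i in seq_len(nrow(ratios))) {
    num <- measured[, ratios$numerator[i]]
    den <- measured[, ratios$denominator[i]]
    bad <- !is.na(den) & den <= 0
    n_bad <- n_bad + sum(bad)
    val <- num / den
    val[bad] <- NA_real_
    out[, ratios$name[i]] <- val
  }
  attr(out, "n_invalid_denominator") <- n_bad
  out
}

#' Lay a panel on a cuboid index
#'
#' Assigns each panel marker to a cell of an `a x b x c` cuboid and derives
#' the `a + b + c` slabs (one per index value of each dimension) used by
#' cuboid-traversal variable selection: every marker belongs to exactly
#' three slabs, one per dimension. Assignment is row-major in panel
#' declaration order and therefore deterministic; an optional permutation
#' seed shuffles panel order beforehand for sensitivity exploration.
#'
#' @param panel a `biomarker_panel`.
#' @param dims integer vector `c(a, b, c)` with `a*b*c >= nrow(panel)`.
#' @param permute_seed optional integer; when given, marker-to-cell
#'   assignment uses a seeded random permutation of panel order.
#' @return An object of class `cuboid_index`: list with `dims`, `cells`
#'   (data.frame marker, i, j, k; zero-based indices) and `slabs` (named
#'   list of marker-name vectors, one per slab).
#' @export
assign_cuboid <- function(panel, dims = c(5L, 5L, 9L), permute_seed = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L))
  nm <- panel_markers(panel)
  n <- length(nm)
  cap <- prod(dims)
  if (cap < n)
    stop("cuboid capacity ", cap, " < panel size ", n,
         "; need dims with product >= ", n)
  if (!is.null(permute_seed)) {
    nm <- withr_seed(permute_seed, sample(nm))
  }
  a <- dims[1]; b <- dims[2]; cc <- dims[3]
  m <- seq_len(n) - 1L
  i <- m %/% (b * cc)
  j <- (m %% (b * cc)) %/% cc
  k <- m %% cc
  cells <- data.frame(marker = nm, i = i, j = j, k = k,
                      stringsAsFactors = FALSE)
  slabs <- c(
    stats::setNames(lapply(seq_len(a) - 1L, function(v) nm[i == v]),
                    paste0("dim1_", seq_len(a) - 1L)),
    stats::setNames(lapply(seq_len(b) - 1L, function(v) nm[j == v]),
                    paste0("dim2_", seq_len(b) - 1L)),
    stats::setNames(lapply(seq_len(cc) - 1L, function(v) nm[k == v]),
                    paste0("dim3_", seq_len(cc) - 1L)))
  slabs <- slabs[vapply(slabs, length, 1L) > 0L]
  structure(list(dims = dims, cells = cells, slabs = slabs),
            class = "cuboid_index")
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.cuboid_index <- function(x, ...) {
  cat(sprintf("cuboid index %d x %d x %d: %d markers, %d slabs\n",
              x$dims[1], x$dims[2], x$dims[3], nrow(x$cells),
              length(x$slabs)))
  invisible(x)
}

#' Read / write a panel spec as TSV
#'
#' The on-disk format is UTF-8 TSV with header columns
#' `name`, `class`, `is_ratio`, `numerator`, `denominator`.
#' @param path file path.
#' @export
read_panel_spec <- function(path) {
  spec <- utils::read.delim(path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8", comment.char = "#")
  spec$is_ratio <- as.logical(spec$is_ratio)
  build_panel(spec)
}

#' @rdname read_panel_spec
#' @param panel a `biomarker_panel` to write.
#' @export
write_panel_spec <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Export a cuboid index as TSV (marker, i, j, k)
#' @param cuboid a `cuboid_index`.
#' @param path file path.
#' @export
write_cuboid_tsv <- function(cuboid, path) {
  utils::write.table(cuboid$cells, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat(sprintf("biomarker panel: %d markers (%d measured, %d ratios)\n",
              nrow(x), attr(x, "n_measured"), attr(x, "n_ratio")))
  invisible(x)
}
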