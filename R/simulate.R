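#' Default per-IE cell-type frequencies
#'
#' IE1 (exhausted) images carry substantial PD-1-high T-cell fractions and
#' NKT cells; IE2 images have almost none of either, with the mass shifted to
#' PD-1-low T cells and B cells. Frequencies sum to 1 within each IE.
#'
#' @return Named list with elements `IE1` and `IE2`, each a named probability
#'   vector over [default_palette()].
#' @export
default_type_frequencies <- function() {
  list(
    IE1 = c(tumor = 0.40, fibroblast = 0.12, endothelial = 0.05, B = 0.05,
            plasma = 0.02, NK = 0.02, NKT = 0.02, pDC = 0.01, migDC = 0.02,
            myeloid = 0.10, Treg = 0.04,
            T_CD4_PD1high = 0.04, T_CD4_PD1low = 0.04,
            T_CD8_PD1high = 0.04, T_CD8_PD1low = 0.03),
    IE2 = c(tumor = 0.40, fibroblast = 0.13, endothelial = 0.05, B = 0.07,
            plasma = 0.03, NK = 0.02, NKT = 0.005, pDC = 0.01, migDC = 0.02,
            myeloid = 0.09, Treg = 0.04,
            T_CD4_PD1high = 0.005, T_CD4_PD1low = 0.06,
            T_CD8_PD1high = 0.005, T_CD8_PD1low = 0.065))
}

#' Simulation configuration
#'
#' Assembles (and checks) the full parameterization of [simulate_tme()]. The
#' defaults encode the study conditions the downstream analyses assume: 1 mm
#' x 1 mm images with several thousand cells, Poisson probe backgrounds
#' calibrated by the `DapB` negative control, a five-fold higher planted
#' cytokine-expresser fraction in IE1 than IE2, planted expresser clusters
#' that become detectable cytokine patches, pairwise spatial
#' attraction/avoidance, TLS-like B-cell aggregates, and (optionally) gene
#' counts carrying myeloid functional signatures and ligand-receptor
#' structure.
#'
#' @param seed integer; fully determines the output.
#' @param n_patients_per_ie patients per immune environment (default 7).
#' @param images_per_patient images per patient (default 4).
#' @param image_size image side length in micrometers (default 1000).
#' @param cells_per_image cells per image (default 4000).
#' @param type_frequencies per-IE named probability vectors over the palette.
#' @param dapb_rate Poisson mean background probe count lambda0 (default 1).
#' @param expresser_boost added Poisson mean for expressing cells (default 5).
#' @param expresser_fraction per-IE named vector: per-cytokine fraction of
#'   cells planted as expressers. Default 0.02 (IE1) / 0.004 (IE2) for every
#'   cytokine: the planted 5:1 contrast.
#' @param patch_intensity list: `mean_per_image` (Poisson mean number of
#'   planted expresser clusters per image per cytokine), `sigma_um` (Gaussian
#'   spread of cluster membership), `size_mean` (cluster size is
#'   3 + Poisson(`size_mean`)). Cluster cells count toward the expresser
#'   quota, so `expresser_fraction` is preserved.
#' @param attraction_pairs data.frame(type_a, type_b, strength) with strength
#'   in `[0, 1]`: the fraction of each type placed by a shared-parent
#'   (Thomas-type) cluster process.
#' @param avoidance_pairs data.frame(type_a, type_b, strength): proposals of
#'   type_b within `avoid_radius` of a type_a cell are resampled with
#'   probability `strength`.
#' @param avoid_radius exclusion radius in micrometers for avoidance pairs.
#' @param cluster_sigma Gaussian displacement (um) around shared parents.
#' @param parents_mean Poisson mean number of shared parents per image.
#' @param tls_spec list: per-IE status probabilities `p_status`, mature disc
#'   radius `mature_radius` (um), immature spread `immature_sigma` (um), and
#'   the fractions of B cells relocated into the aggregate.
#' @param signature_spec list controlling gene simulation for the signature
#'   module: `positive_fraction` of myeloid/migDC cells designated
#'   signature-positive, `elevation` multiplier on attraction and suppression
#'   genes in those cells, `base_mean` per-gene Poisson mean, `n_filler`
#'   unstructured genes, `libsize_sd` lognormal per-cell library factor sd.
#' @param lr_spec list controlling ligand-receptor structure: `boosted_pairs`
#'   (names `<ligand>_<receptor>` elevated in IE1), `ie2_boosted` (elevated in
#'   IE2), `boost` multiplier, `sender_factor`/`receiver_factor` multipliers
#'   for ligands in myeloid-lineage senders and receptors in T/NK receivers,
#'   `patient_sd` lognormal per-patient-per-gene sd.
#' @param include_genes logical; simulate `gx_` gene counts (default `TRUE`).
#'   Spatial-only studies can disable this for speed.
#' @param cytokines cytokine probe names (excluding `DapB`).
#' @param palette cell-type labels.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_patients_per_ie = 7L,
                       images_per_patient = 4L,
                       image_size = 1000,
                       cells_per_image = 4000L,
                       type_frequencies = default_type_frequencies(),
                       dapb_rate = 1.0,
                       expresser_boost = 5.0,
                       expresser_fraction = NULL,
                       patch_intensity = list(mean_per_image = 1, sigma_um = 15,
                                              size_mean = 5),
                       attraction_pairs = data.frame(
                         type_a = c("migDC", "fibroblast"),
                         type_b = c("T_CD8_PD1high", "endothelial"),
                         strength = c(0.8, 0.6)),
                       avoidance_pairs = data.frame(
                         type_a = "tumor", type_b = "B", strength = 0.8),
                       avoid_radius = 40,
                       cluster_sigma = 25,
                       parents_mean = 6,
                       tls_spec = list(
                         p_status = list(
                           IE1 = c(none = 0.6, immature = 0.3, mature = 0.1),
                           IE2 = c(none = 0.6, immature = 0.1, mature = 0.3)),
                         mature_radius = 80, immature_sigma = 120,
                         mature_fraction = 0.7, immature_fraction = 0.5),
                       signature_spec = list(positive_fraction = 0.3,
                                             elevation = 6, base_mean = 0.3,
                                             n_filler = 20, libsize_sd = 0.3),
                       lr_spec = list(
                         boosted_pairs = c("CD274_PDCD1", "CD80_CTLA4",
                                           "LGALS9_HAVCR2", "PVR_TIGIT",
                                           "CXCL9_CXCR3", "CCL5_CCR5",
                                           "CSF1_CSF1R", "IL15_IL15RA"),
                         ie2_boosted = c("FLT3LG_FLT3"),
                         boost = 4, sender_factor = 3, receiver_factor = 3,
                         patient_sd = 0.3),
                       include_genes = TRUE,
                       cytokines = default_cytokines(),
                       palette = default_palette()) {
  if (is.null(expresser_fraction)) {
    expresser_fraction <- list(
      IE1 = stats::setNames(rep(0.02, length(cytokines)), cytokines),
      IE2 = stats::setNames(rep(0.004, length(cytokines)), cytokines))
  }
  cfg <- as.list(environment())
  for (ie in IE_LEVELS) {
    f <- type_frequencies[[ie]]
    if (is.null(f) || abs(sum(f) - 1) > 1e-8)
      stop("configuration error: type_frequencies$", ie, " must sum to 1")
    if (!all(names(f) %in% palette))
      stop("configuration error: type frequency for unknown cell type")
    if (any(f < 0)) stop("configuration error: negative type frequency")
  }
  if (dapb_rate < 0 || expresser_boost < 0)
    stop("configuration error: rates must be >= 0")
  if (nrow(attraction_pairs) && any(attraction_pairs$strength < 0 |
                                    attraction_pairs$strength > 1))
    stop("configuration error: attraction strength must be in [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

# shipped gene roles ------------------------------------------------------

sig_file <- function(name) {
  system.file("extdata", "signatures", paste0(name, ".txt"),
              package = "spatmilieu", mustWork = TRUE)
}

#' Shipped gene signatures
#'
#' Reads the four myeloid functional signatures shipped with the package
#' (T-cell attraction, T-cell suppression, M1, M2). The lists are
#' literature-role placeholders shipped as editable one-gene-per-line text
#' files; users analyzing real data should substitute their own curated
#' lists.
#'
#' @return Named list of [signature_def()] objects.
#' @export
default_signatures <- function() {
  nm <- c("t_attraction", "t_suppression", "m1", "m2")
  out <- lapply(nm, function(n) signature_def(n, readLines(sig_file(n))))
  stats::setNames(out, nm)
}

#' Shipped ligand-receptor pair list
#'
#' A small curated list of ligand-receptor pairs covering immune checkpoints,
#' chemokine axes, and cytokine-receptor interactions relevant to exhausted
#' tumor immune environments, with an annotation column. Users may substitute
#' a larger database with the same columns.
#'
#' @return data.frame(ligand, receptor, annotation).
#' @export
default_lr_pairs <- function() {
  utils::read.csv(system.file("extdata", "lr_pairs.csv",
                              package = "spatmilieu", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

# gene palette used by the generator: signature genes + LR genes + filler
sim_gene_palette <- function(cfg) {
  sigs <- default_signatures()
  lr <- default_lr_pairs()
  filler <- sprintf("FILLER%02d", seq_len(cfg$signature_spec$n_filler))
  unique(c(unlist(lapply(sigs, function(s) s$genes)),
           lr$ligand, lr$receptor, filler))
}

# simulate ----------------------------------------------------------------

#' Simulate a tumor-immune-microenvironment dataset with known ground truth
#'
#' Draws a full multi-patient, multi-image dataset under the configuration in
#' `cfg` and returns both the dataset and the ground truth that was planted
#' into it, so that every downstream stage can be scored against the truth.
#' Identical configurations (including seed) give identical output.
#'
#' Placement model per image: cell types are drawn i.i.d. from the IE's type
#' frequencies; positions start uniform; for each attraction pair a
#' `strength` fraction of both types is re-placed around shared Gaussian
#' parents (Thomas-type process); avoidance pairs thin type-b proposals near
#' type-a cells by uniform resampling; TLS images relocate part of their B
#' cells into a dense disc (mature) or loose Gaussian aggregate (immature).
#' Every cell receives `cy_DapB ~ Poisson(lambda0)` and, per cytokine,
#' `Poisson(lambda0)` if non-expressing or `Poisson(lambda0 + boost)` if
#' expressing. Expressers are planted partly in spatial clusters (seed cell
#' plus Gaussian-weighted nearby cells) and partly dispersed; in mature-TLS
#' images the CXCL13 clusters are anchored at the TLS so that CXCL13+ cells
#' there sit in patches, while immature-TLS images get only dispersed CXCL13
#' expressers.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `dataset` (a `tme_dataset`) and `truth`, a list
#'   with `expresser_flags` (long data.frame cell_id/cytokine of planted
#'   expressers), `planted_patch_members` (data.frame image_id, cytokine,
#'   cluster, cell_id), `pair_effects` (the attraction/avoidance table used),
#'   `signature_positive_cells` (cell_ids with elevated signature genes), and
#'   `tls_centers`.
#' @export
simulate_tme <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  n_pat <- cfg$n_patients_per_ie
  patients <- data.frame(
    patient_id = sprintf("P%02d", seq_len(2 * n_pat)),
    ie_label = rep(IE_LEVELS, each = n_pat),
    grade = sample(1:3, 2 * n_pat, replace = TRUE),
    stringsAsFactors = FALSE)

  img_rows <- list(); cell_rows <- list()
  flags_rows <- list(); patch_rows <- list(); tls_rows <- list()
  sigpos_all <- character(0)
  size <- cfg$image_size
  n <- cfg$cells_per_image
  cyt <- cfg$cytokines
  genes <- if (cfg$include_genes) sim_gene_palette(cfg) else character(0)
  sigs <- if (cfg$include_genes) default_signatures() else NULL
  lrdb <- if (cfg$include_genes) default_lr_pairs() else NULL
  # per-patient per-gene lognormal factors
  patfac <- if (cfg$include_genes)
    matrix(stats::rlnorm(2 * n_pat * length(genes), 0, cfg$lr_spec$patient_sd),
           nrow = 2 * n_pat, dimnames = list(patients$patient_id, genes))
  else NULL

  img_id <- 0L
  for (p in seq_len(nrow(patients))) {
    ie <- patients$ie_label[p]
    freq <- cfg$type_frequencies[[ie]]
    for (im in seq_len(cfg$images_per_patient)) {
      img_id <- img_id + 1L
      iid <- sprintf("img%03d", img_id)
      types <- sample(names(freq), n, replace = TRUE, prob = freq)
      x <- stats::runif(n, 0, size); y <- stats::runif(n, 0, size)

      # attraction: shared-parent cluster placement
      if (nrow(cfg$attraction_pairs)) for (ap in seq_len(nrow(cfg$attraction_pairs))) {
        a <- cfg$attraction_pairs$type_a[ap]; b <- cfg$attraction_pairs$type_b[ap]
        th <- cfg$attraction_pairs$strength[ap]
        npar <- max(1L, stats::rpois(1, cfg$parents_mean))
        px <- stats::runif(npar, 0, size); py <- stats::runif(npar, 0, size)
        for (tt in c(a, b)) {
          ii <- which(types == tt)
          nsel <- round(th * length(ii))
          if (nsel < 1) next
          sel <- sample(ii, nsel)
          par <- sample.int(npar, nsel, replace = TRUE)
          x[sel] <- clamp(px[par] + stats::rnorm(nsel, 0, cfg$cluster_sigma), 0, size)
          y[sel] <- clamp(py[par] + stats::rnorm(nsel, 0, cfg$cluster_sigma), 0, size)
        }
      }

      # avoidance: thin type-b proposals near type-a cells
      if (nrow(cfg$avoidance_pairs)) for (vp in seq_len(nrow(cfg$avoidance_pairs))) {
        a <- cfg$avoidance_pairs$type_a[vp]; b <- cfg$avoidance_pairs$type_b[vp]
        st <- cfg$avoidance_pairs$strength[vp]
        ia <- which(types == a); ib <- which(types == b)
        if (!length(ia) || !length(ib)) next
        for (round_ in 1:10) {
          comb_x <- c(x[ia], x[ib]); comb_y <- c(y[ia], y[ib])
          pw <- pairs_within(comb_x, comb_y, cfg$avoid_radius)
          na_ <- length(ia)
          viol <- unique(c(pw$j[pw$i <= na_ & pw$j > na_] - na_,
                           pw$i[pw$j <= na_ & pw$i > na_] - na_))
          if (!length(viol)) break
          move <- viol[stats::runif(length(viol)) < st]
          if (!length(move)) break
          x[ib[move]] <- stats::runif(length(move), 0, size)
          y[ib[move]] <- stats::runif(length(move), 0, size)
        }
      }

      # TLS aggregate
      tls <- sample(names(cfg$tls_spec$p_status[[ie]]), 1,
                    prob = cfg$tls_spec$p_status[[ie]])
      tls_cx <- NA_real_; tls_cy <- NA_real_
      if (tls != "none") {
        margin <- if (tls == "mature") cfg$tls_spec$mature_radius + 20 else 150
        # TLS are stromal structures: among candidate centers, take the one
        # with the fewest tumor cells nearby
        ccx <- stats::runif(20, margin, size - margin)
        ccy <- stats::runif(20, margin, size - margin)
        tum <- which(types == "tumor")
        load <- vapply(seq_len(20), function(ci)
          sum((x[tum] - ccx[ci])^2 + (y[tum] - ccy[ci])^2 < 150^2), numeric(1))
        best <- which.min(load)
        tls_cx <- ccx[best]; tls_cy <- ccy[best]
        ib <- which(types == "B")
        frac <- if (tls == "mature") cfg$tls_spec$mature_fraction
                else cfg$tls_spec$immature_fraction
        nmove <- round(frac * length(ib))
        if (nmove >= 1) {
          sel <- sample(ib, nmove)
          if (tls == "mature") {
            rr <- cfg$tls_spec$mature_radius * sqrt(stats::runif(nmove))
            ang <- stats::runif(nmove, 0, 2 * pi)
            x[sel] <- clamp(tls_cx + rr * cos(ang), 0, size)
            y[sel] <- clamp(tls_cy + rr * sin(ang), 0, size)
          } else {
            x[sel] <- clamp(tls_cx + stats::rnorm(nmove, 0, cfg$tls_spec$immature_sigma), 0, size)
            y[sel] <- clamp(tls_cy + stats::rnorm(nmove, 0, cfg$tls_spec$immature_sigma), 0, size)
          }
        }
      }
      tls_rows[[img_id]] <- data.frame(image_id = iid, tls_status = tls,
                                       x_um = tls_cx, y_um = tls_cy,
                                       stringsAsFactors = FALSE)

      radius <- clamp(stats::rlnorm(n, log(5), 0.35), 2, 15)
      cell_id <- sprintf("%s_c%04d", iid, seq_len(n))

      # planted cytokine expressers: clustered (counted against quota) + dispersed
      E <- matrix(FALSE, n, length(cyt), dimnames = list(NULL, cyt))
      for (k in seq_along(cyt)) {
        ck <- cyt[k]
        f <- cfg$expresser_fraction[[ie]][[ck]]
        quota <- stats::rbinom(1, n, f)
        planted <- integer(0)
        ncl <- stats::rpois(1, cfg$patch_intensity$mean_per_image)
        if (ck == "CXCL13" && tls == "mature") ncl <- max(1L, ncl)
        if (ck == "CXCL13" && tls == "immature") ncl <- 0L
        cl_idx <- 0L
        while (ncl > 0 && quota - length(planted) >= 3) {
          ncl <- ncl - 1L
          csize <- min(3 + stats::rpois(1, cfg$patch_intensity$size_mean),
                       quota - length(planted))
          avail <- setdiff(seq_len(n), planted)
          if (ck == "CXCL13" && tls == "mature") {
            seed_cell <- avail[which.min((x[avail] - tls_cx)^2 + (y[avail] - tls_cy)^2)]
          } else seed_cell <- sample(avail, 1)
          d2 <- (x[avail] - x[seed_cell])^2 + (y[avail] - y[seed_cell])^2
          w <- exp(-d2 / (2 * cfg$patch_intensity$sigma_um^2))
          # CXCL13 at a mature TLS is carried by follicular-helper-like T
          # cells sitting inside the B-cell aggregate
          if (ck == "CXCL13" && tls == "mature")
            w <- w * ifelse(grepl("^T_CD", types[avail]), 10, 1)
          w[avail == seed_cell] <- 0
          pickable <- avail[w > 0]
          nw <- min(csize - 1L, length(pickable))
          members <- c(seed_cell,
                       if (nw > 0) sample(pickable, nw, prob = w[w > 0]) else integer(0))
          planted <- c(planted, members)
          cl_idx <- cl_idx + 1L
          patch_rows[[length(patch_rows) + 1L]] <- data.frame(
            image_id = iid, cytokine = ck, cluster = cl_idx,
            cell_id = cell_id[members], stringsAsFactors = FALSE)
        }
        extra <- quota - length(planted)
        if (extra > 0)
          planted <- c(planted, sample(setdiff(seq_len(n), planted), extra))
        E[planted, k] <- TRUE
      }
      for (k in seq_along(cyt)) {
        w <- which(E[, k])
        if (length(w))
          flags_rows[[length(flags_rows) + 1L]] <- data.frame(
            cell_id = cell_id[w], cytokine = cyt[k], stringsAsFactors = FALSE)
      }

      # probe counts
      cy <- matrix(stats::rpois(n * length(cyt),
                                cfg$dapb_rate + cfg$expresser_boost * E),
                   n, length(cyt), dimnames = list(NULL, paste0("cy_", cyt)))
      dapb <- stats::rpois(n, cfg$dapb_rate)

      # signature-positive myeloid-lineage cells (drives markers and genes)
      myel <- which(types %in% c("myeloid", "migDC"))
      sigpos <- sort(sample(myel, round(cfg$signature_spec$positive_fraction * length(myel))))
      sigpos_all <- c(sigpos_all, cell_id[sigpos])

      # marker intensities (lognormal; type-informative)
      mk <- function(hi_idx, hi = 8, lo = 0.5, sd = 0.4) {
        m <- stats::rlnorm(n, log(lo), sd)
        m[hi_idx] <- stats::rlnorm(length(hi_idx), log(hi), sd)
        m
      }
      markers <- data.frame(
        mk_PD1 = mk(which(types %in% c("T_CD4_PD1high", "T_CD8_PD1high"))),
        mk_CD20 = mk(which(types == "B")),
        mk_LAMP3 = mk(which(types == "migDC")),
        mk_panCK = mk(which(types == "tumor")),
        mk_PDL1 = mk(sigpos), mk_IDO1 = mk(sigpos))

      df <- data.frame(cell_id = cell_id, image_id = iid, x_um = x, y_um = y,
                       radius_um = radius, cell_type = types,
                       stringsAsFactors = FALSE)
      df <- cbind(df, markers, cy_DapB = dapb, as.data.frame(cy))

      if (cfg$include_genes) {
        gm <- sim_gene_means(types, genes, sigs, lrdb, cfg, ie, sigpos)
        gm <- gm * patfac[rep(patients$patient_id[p], n), , drop = FALSE]
        lib <- stats::rlnorm(n, 0, cfg$signature_spec$libsize_sd)
        gm <- gm * lib
        gx <- matrix(stats::rpois(length(gm), gm), n, length(genes),
                     dimnames = list(NULL, paste0("gx_", genes)))
        df <- cbind(df, as.data.frame(gx))
      }
      cell_rows[[img_id]] <- df
      img_rows[[img_id]] <- data.frame(
        image_id = iid, patient_id = patients$patient_id[p],
        width_um = size, height_um = size, tls_status = tls,
        stringsAsFactors = FALSE)
    }
  }

  ds <- tme_dataset(do.call(rbind, cell_rows), do.call(rbind, img_rows),
                    patients, palette = cfg$palette, cytokines = cyt)
  pair_effects <- rbind(
    if (nrow(cfg$attraction_pairs))
      cbind(cfg$attraction_pairs, effect = "attraction"),
    if (nrow(cfg$avoidance_pairs))
      cbind(cfg$avoidance_pairs, effect = "avoidance"))
  truth <- list(
    expresser_flags = if (length(flags_rows)) do.call(rbind, flags_rows)
      else data.frame(cell_id = character(0), cytokine = character(0)),
    planted_patch_members = if (length(patch_rows)) do.call(rbind, patch_rows)
      else data.frame(image_id = character(0), cytokine = character(0),
                      cluster = integer(0), cell_id = character(0)),
    pair_effects = pair_effects,
    signature_positive_cells = sigpos_all,
    tls_centers = do.call(rbind, tls_rows))
  list(dataset = ds, truth = truth)
}

# per-cell x gene Poisson mean matrix before patient/library factors
sim_gene_means <- function(types, genes, sigs, lrdb, cfg, ie, sigpos) {
  n <- length(types)
  base <- cfg$signature_spec$base_mean
  gm <- matrix(base, n, length(genes), dimnames = list(NULL, genes))
  myel <- types %in% c("myeloid", "migDC")
  tnk <- types %in% c("T_CD4_PD1high", "T_CD4_PD1low", "T_CD8_PD1high",
                      "T_CD8_PD1low", "Treg", "NK", "NKT")
  # ligand/receptor cell-type structure
  for (r in seq_len(nrow(lrdb))) {
    lg <- lrdb$ligand[r]; rc <- lrdb$receptor[r]
    key <- paste(lg, rc, sep = "_")
    gm[myel, lg] <- gm[myel, lg] * cfg$lr_spec$sender_factor
    gm[tnk, rc] <- gm[tnk, rc] * cfg$lr_spec$receiver_factor
    bf <- if (key %in% cfg$lr_spec$boosted_pairs && ie == "IE1") cfg$lr_spec$boost
          else if (key %in% cfg$lr_spec$ie2_boosted && ie == "IE2") cfg$lr_spec$boost
          else 1
    if (bf != 1) {
      gm[myel, lg] <- gm[myel, lg] * bf
      gm[tnk, rc] <- gm[tnk, rc] * bf
    }
  }
  # signature elevation in designated myeloid cells
  el <- cfg$signature_spec$elevation
  sg <- unique(c(sigs$t_attraction$genes, sigs$t_suppression$genes))
  sg <- intersect(sg, genes)
  gm[sigpos, sg] <- gm[sigpos, sg] * el
  # mild M1/M2 elevation in all myeloid-lineage cells
  mg <- intersect(unique(c(sigs$m1$genes, sigs$m2$genes)), genes)
  gm[myel, mg] <- gm[myel, mg] * 2
  gm
}

# toy fixtures -------------------------------------------------------------

#' Hand-specified deterministic micro-datasets
#'
#' A catalogue of tiny fixtures with exactly known spatial structure, used to
#' pin down the neighbor, patch and milieu definitions:
#' \describe{
#'   \item{`three_cell_line`}{3 CXCL13-expressing T cells at x = 0, 20, 40 um
#'     on a horizontal line: one specific patch at the 25 um neighbor rule.}
#'   \item{`segregated_types`}{two cell types in dense blocks in opposite
#'     image halves: pairwise avoidance between, interaction within.}
#'   \item{`two_patch_image`}{two planted 5-cell CXCL13 patches 200 um apart
#'     plus 5 isolated CXCL13+ T cells and non-expressing filler cells.}
#' }
#'
#' @param name fixture name.
#' @return list(dataset, truth) as in [simulate_tme()].
#' @export
toy_fixture <- function(name = c("three_cell_line", "segregated_types",
                                 "two_patch_image")) {
  name <- match.arg(name)
  mk_ds <- function(x, y, type, expr, size = 1000) {
    n <- length(x)
    cells <- data.frame(
      cell_id = sprintf("t_c%03d", seq_len(n)), image_id = "img001",
      x_um = x, y_um = y, radius_um = 5, cell_type = type,
      cy_DapB = 0, cy_CXCL13 = ifelse(expr, 30, 0),
      stringsAsFactors = FALSE)
    images <- data.frame(image_id = "img001", patient_id = "P01",
                         width_um = size, height_um = size,
                         tls_status = "none", stringsAsFactors = FALSE)
    patients <- data.frame(patient_id = "P01", ie_label = "IE1", grade = 2L,
                           stringsAsFactors = FALSE)
    ds <- tme_dataset(cells, images, patients, cytokines = "CXCL13")
    truth <- list(
      expresser_flags = data.frame(cell_id = cells$cell_id[expr],
                                   cytokine = rep("CXCL13", sum(expr)),
                                   stringsAsFactors = FALSE),
      planted_patch_members = data.frame(
        image_id = character(0), cytokine = character(0),
        cluster = integer(0), cell_id = character(0)),
      pair_effects = NULL, signature_positive_cells = character(0),
      tls_centers = NULL)
    list(dataset = ds, truth = truth)
  }
  if (name == "three_cell_line") {
    out <- mk_ds(x = c(0, 20, 40), y = c(0, 0, 0),
                 type = rep("T_CD4_PD1low", 3), expr = rep(TRUE, 3))
    out$truth$planted_patch_members <- data.frame(
      image_id = "img001", cytokine = "CXCL13", cluster = 1L,
      cell_id = out$dataset$cells$cell_id, stringsAsFactors = FALSE)
    return(out)
  }
  if (name == "segregated_types") {
    # dense 10 x 20 grids, 15 um spacing, in opposite halves
    gx <- rep(seq(0, by = 15, length.out = 10), times = 20)
    gy <- rep(seq(0, by = 15, length.out = 20), each = 10)
    x <- c(gx + 100, gx + 750); y <- c(gy + 350, gy + 350)
    type <- rep(c("tumor", "B"), each = 200)
    return(mk_ds(x, y, type, expr = rep(FALSE, 400)))
  }
  # two_patch_image: patches at (200, 500) and (400, 500), 5 cells each at
  # 15 um spacing; 5 isolated expressers > 25 um from everything; filler
  px1 <- 200 + 15 * (0:4); px2 <- 400 + 15 * (0:4)
  iso_x <- c(100, 300, 500, 700, 900); iso_y <- rep(100, 5)
  fill_x <- c(150, 350, 550, 750, 850, 650); fill_y <- rep(900, 6)
  x <- c(px1, px2, iso_x, fill_x)
  y <- c(rep(500, 10), iso_y, fill_y)
  type <- c(rep("T_CD4_PD1low", 15), rep("tumor", 6))
  expr <- c(rep(TRUE, 15), rep(FALSE, 6))
  out <- mk_ds(x, y, type, expr)
  out$truth$planted_patch_members <- data.frame(
    image_id = "img001", cytokine = "CXCL13",
    cluster = rep(1:2, each = 5),
    cell_id = out$dataset$cells$cell_id[1:10], stringsAsFactors = FALSE)
  out
}

#' Convert ground-truth expresser flags into a call table
#'
#' Builds a `CytokineCallTable`-shaped data.frame directly from a simulation
#' ground truth, bypassing statistical calling. Useful to test the spatial
#' stages (patches, milieus, membership statistics) in isolation from the
#' calling stage.
#'
#' @param ds the `tme_dataset` the truth belongs to.
#' @param truth the `truth` element returned by [simulate_tme()] or
#'   [toy_fixture()].
#' @return data.frame(cell_id, cytokine, d, p, q, expressed) covering every
#'   (cell, cytokine) combination.
#' @export
calls_from_truth <- function(ds, truth) {
  grid <- expand.grid(cell_id = ds$cells$cell_id, cytokine = ds$cytokines,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(grid$cell_id, grid$cytokine)
  tkey <- paste(truth$expresser_flags$cell_id, truth$expresser_flags$cytokine)
  expressed <- key %in% tkey
  data.frame(grid, d = NA_real_, p = ifelse(expressed, 0, 1),
             q = ifelse(expressed, 0, 1), expressed = expressed,
             stringsAsFactors = FALSE)
}
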