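#' Parametric disease model for two-point linkage
#'
#' The published mapping model: fully penetrant autosomal dominant inheritance
#' with no phenocopies and disease allele frequency 1e-4, analysed
#' affected-only (unaffected phenotypes treated as unknown, which makes the
#' LOD robust to incomplete penetrance).
#'
#' @param disease_allele_freq Population frequency of the disease allele, in
#'   (0, 1). Default 1e-4.
#' @param penetrance Length-3 vector: P(affected) given 0, 1, 2 copies of the
#'   disease allele. Default `c(0, 1, 1)` (dominant, fully penetrant, no
#'   phenocopies — `penetrance[1]` is the phenocopy rate).
#' @param affected_only If `TRUE` (default), unaffected individuals'
#'   phenotypes are treated as unknown.
#' @return An object of class `linkage_model`.
#' @export
linkage_model <- function(disease_allele_freq = 1e-4,
                          penetrance = c(0, 1, 1),
                          affected_only = TRUE) {
  if (!(disease_allele_freq > 0 && disease_allele_freq < 1)) {
    stop_input("`disease_allele_freq` must be in (0,1)")
  }
  penetrance <- as.numeric(penetrance)
  if (length(penetrance) != 3L || anyNA(penetrance) ||
      any(penetrance < 0 | penetrance > 1)) {
    stop_input("`penetrance` must be three probabilities in [0,1]")
  }
  structure(list(disease_allele_freq = disease_allele_freq,
                 penetrance = penetrance,
                 affected_only = isTRUE(affected_only)),
            class = "linkage_model")
}

#' Marker data for a two-point analysis
#'
#' A codominant marker: population allele frequencies plus observed unordered
#' genotypes. Genotypes default to the pedigree's first stored marker.
#'
#' @param freqs Numeric vector of allele frequencies (one per allele code,
#'   must sum to 1 within 1e-8).
#' @param genotypes Optional `n x 2` integer matrix of allele codes
#'   (`NA` = untyped); when `NULL`, taken from the pedigree at analysis time.
#' @param name Optional name of the pedigree marker to use when
#'   `genotypes = NULL`.
#' @return An object of class `marker_data`.
#' @export
marker_data <- function(freqs, genotypes = NULL, name = NULL) {
  freqs <- as.numeric(freqs)
  if (length(freqs) < 1L || anyNA(freqs) || any(freqs <= 0)) {
    stop_input("marker allele frequencies must be positive")
  }
  if (abs(sum(freqs) - 1) > 1e-8) stop_input("marker allele frequencies must sum to 1")
  if (!is.null(genotypes)) {
    genotypes <- as.matrix(genotypes)
    storage.mode(genotypes) <- "integer"
    if (ncol(genotypes) != 2L) stop_input("genotypes must be an n x 2 matrix")
    if (any(!is.na(genotypes) & (genotypes < 1 | genotypes > length(freqs)))) {
      stop_input("genotype allele codes must index `freqs`")
    }
  }
  structure(list(freqs = freqs, genotypes = genotypes, name = name),
            class = "marker_data")
}

# ---- joint disease-marker state space -------------------------------------
# haplotype h in 1..2k: disease allele d in {1 = disease, 2 = wild type},
# marker allele m in 1..k, h = (d-1)*k + m.
# ordered genotype g in 1..G, G = (2k)^2: g = (h_pat - 1)*2k + h_mat.

hap_space <- function(k) {
  H <- 2L * k
  d <- rep(1:2, each = k)
  m <- rep(seq_len(k), 2L)
  G <- H * H
  g_pat <- rep(seq_len(H), each = H)
  g_mat <- rep(seq_len(H), times = H)
  list(k = k, H = H, G = G, hap_d = d, hap_m = m, g_pat = g_pat, g_mat = g_mat,
       n_dis = (d[g_pat] == 1L) + (d[g_mat] == 1L),
       m_pat = m[g_pat], m_mat = m[g_mat])
}

.trans_cache <- new.env(parent = emptyenv())

# H x G matrix: P(transmitted haplotype = h | parent genotype g) at
# recombination fraction theta; cached per (k, theta) since LOD grids reuse
# the same thetas across many pedigrees
transmission_matrix <- function(sp, theta) {
  key <- sprintf("%d:%.17g", sp$k, theta)
  hit <- get0(key, envir = .trans_cache)
  if (!is.null(hit)) return(hit)
  A <- transmission_matrix_build(sp, theta)
  assign(key, A, envir = .trans_cache)
  A
}

transmission_matrix_build <- function(sp, theta) {
  A <- matrix(0, sp$H, sp$G)
  hap_of <- function(d, m) (d - 1L) * sp$k + m
  for (g in seq_len(sp$G)) {
    h1 <- sp$g_pat[g]; h2 <- sp$g_mat[g]
    d1 <- sp$hap_d[h1]; m1 <- sp$hap_m[h1]
    d2 <- sp$hap_d[h2]; m2 <- sp$hap_m[h2]
    A[h1, g] <- A[h1, g] + (1 - theta) / 2
    A[h2, g] <- A[h2, g] + (1 - theta) / 2
    A[hap_of(d1, m2), g] <- A[hap_of(d1, m2), g] + theta / 2
    A[hap_of(d2, m1), g] <- A[hap_of(d2, m1), g] + theta / 2
  }
  A
}

# per-individual weight over genotype states: marker observation x penetrance,
# times Hardy-Weinberg/linkage-equilibrium founder prior for founders
state_weights <- function(ped, sp, geno, model, hap_prior) {
  pen <- model$penetrance
  founders <- is_founder(ped)
  lapply(seq_len(ped$n), function(i) {
    w <- rep(1, sp$G)
    a <- geno[i, ]
    if (!anyNA(a)) {
      ok <- (sp$m_pat == a[1] & sp$m_mat == a[2]) |
            (sp$m_pat == a[2] & sp$m_mat == a[1])
      w[!ok] <- 0
    }
    aff <- ped$affection[i]
    if (model$affected_only && aff == "unaffected") aff <- "unknown"
    if (aff == "affected") w <- w * pen[sp$n_dis + 1L]
    if (aff == "unaffected") w <- w * (1 - pen[sp$n_dis + 1L])
    if (founders[i]) w <- w * hap_prior[sp$g_pat] * hap_prior[sp$g_mat]
    w
  })
}

prepare_two_point <- function(ped, marker, model) {
  stopifnot(inherits(ped, "pedigree"), inherits(model, "linkage_model"))
  if (length(unique(ped$family)) != 1L) {
    stop_input("two-point analysis takes one family; use split_families()")
  }
  if (!inherits(marker, "marker_data")) stop_input("`marker` must be marker_data()")
  geno <- marker$genotypes
  if (is.null(geno)) {
    if (length(ped$markers) == 0L) stop_input("pedigree has no stored markers")
    nm <- marker$name %||% names(ped$markers)[1]
    if (!nm %in% names(ped$markers)) stop_input("pedigree has no marker '%s'", nm)
    geno <- ped$markers[[nm]]
  }
  if (nrow(geno) != ped$n) stop_input("marker genotypes must have one row per individual")
  if (any(!is.na(geno) & (geno < 1 | geno > length(marker$freqs)))) {
    stop_input("marker allele codes exceed the frequency vector")
  }
  if (has_pedigree_loop(ped)) {
    stop_input("unsupported structure: pedigree contains a loop")
  }
  k <- length(marker$freqs)
  sp <- hap_space(k)
  p <- model$disease_allele_freq
  hap_prior <- c(p * marker$freqs, (1 - p) * marker$freqs)  # linkage equilibrium
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  list(sp = sp, geno = geno, hap_prior = hap_prior, fa = fa, mo = mo,
       weights = state_weights(ped, sp, geno, model, hap_prior))
}

# marriage-graph loop test: individuals and mating units as nodes; a pedigree
# is loop-free iff that graph is a forest
has_pedigree_loop <- function(ped) {
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  kids <- which(!is.na(fa))
  if (length(kids) == 0L) return(FALSE)
  mate_key <- paste(pmin(fa[kids], mo[kids]), pmax(fa[kids], mo[kids]))
  mate_id <- ped$n + as.integer(factor(mate_key, levels = unique(mate_key)))
  edges <- rbind(cbind(fa[kids], mate_id), cbind(mo[kids], mate_id),
                 cbind(kids, mate_id))
  edges <- unique(edges)
  n_nodes <- ped$n + length(unique(mate_id))
  parent <- seq_len(n_nodes)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a == b) return(TRUE)
    parent[a] <- b
  }
  FALSE
}

#' Two-point pedigree log10-likelihood by peeling
#'
#' Exact likelihood of the observed marker genotypes and phenotypes under the
#' joint disease-marker model at recombination fraction `theta`, computed by
#' variable elimination over per-individual joint haplotype-pair states
#' (pedigree peeling in the Elston-Stewart tradition). Founder priors are
#' Hardy-Weinberg with linkage-equilibrium haplotype frequencies; transmission
#' uses a sex-averaged `theta`; unknown phenotypes contribute a factor of 1.
#'
#' @param ped A single-family, loop-free [pedigree].
#' @param marker A [marker_data].
#' @param theta Recombination fraction in `[0, 0.5]`.
#' @param model A [linkage_model].
#' @return log10 likelihood (`-Inf`, with a `diagnostic` attribute, when the
#'   data are Mendelian-impossible under the model).
#' @export
pedigree_log_likelihood <- function(ped, marker, theta, model = linkage_model()) {
  if (!(is.numeric(theta) && length(theta) == 1L && theta >= 0 && theta <= 0.5)) {
    stop_input("`theta` must be in [0, 0.5]")
  }
  pre <- prepare_two_point(ped, marker, model)
  peel_likelihood(pre, transmission_matrix(pre$sp, theta))
}

# ---- variable elimination over the pedigree factor graph -------------------

peel_likelihood <- function(pre, A) {
  sp <- pre$sp; G <- sp$G
  n <- length(pre$weights)
  unary <- pre$weights
  # transmission factors: one per (child, parent, strand)
  trans <- list()
  for (i in seq_len(n)) {
    if (!is.na(pre$fa[i])) {
      trans[[length(trans) + 1L]] <- list(child = i, parent = pre$fa[i], comp = "pat")
      trans[[length(trans) + 1L]] <- list(child = i, parent = pre$mo[i], comp = "mat")
    }
  }
  generics <- list()  # each: list(vars = int vector, tab = array)
  alive <- rep(TRUE, n)
  logshift <- 0

  comp_rows <- list(pat = sp$g_pat, mat = sp$g_mat)
  dense_trans <- function(tf) {
    # factor over (child, parent): T[g_c, g_p] = A[component(g_c), g_p]
    list(vars = c(tf$child, tf$parent), tab = A[comp_rows[[tf$comp]], , drop = FALSE])
  }

  neighbors_of <- function(x) {
    nb <- integer(0)
    for (tf in trans) {
      if (tf$child == x) nb <- c(nb, tf$parent)
      if (tf$parent == x) nb <- c(nb, tf$child)
    }
    for (gf in generics) if (x %in% gf$vars) nb <- c(nb, setdiff(gf$vars, x))
    unique(nb)
  }

  while (any(alive)) {
    vars_left <- which(alive)
    nbs <- lapply(vars_left, neighbors_of)
    costs <- lengths(nbs)
    # prefer leaf children (cheap matrix shortcut), then smallest scope
    is_leaf_child <- vapply(vars_left, function(x) {
      !any(vapply(trans, function(tf) tf$parent == x, logical(1)))
    }, logical(1))
    ord <- order(costs, !is_leaf_child)
    x <- vars_left[ord[1]]
    nb <- nbs[[ord[1]]]

    my_trans_i <- which(vapply(trans, function(tf) tf$child == x || tf$parent == x, logical(1)))
    my_gen_i <- which(vapply(generics, function(gf) x %in% gf$vars, logical(1)))

    u <- unary[[x]]
    # fold generic factors whose scope is exactly {x} into the unary
    all_gen_i <- my_gen_i
    fold <- my_gen_i[vapply(generics[my_gen_i], function(gf) {
      length(gf$vars) == 1L && gf$vars == x
    }, logical(1))]
    for (gi in fold) u <- u * as.numeric(generics[[gi]]$tab)
    my_gen_i <- setdiff(my_gen_i, fold)

    tfs <- trans[my_trans_i]
    shortcut <- length(my_gen_i) == 0L && length(tfs) == 2L &&
      all(vapply(tfs, function(tf) tf$child == x, logical(1))) &&
      tfs[[1]]$parent != tfs[[2]]$parent
    if (shortcut) {
      # R[g_F, g_M] = sum_{hp,hm} A[hp, g_F] * U[hp, hm] * A[hm, g_M]
      pat_tf <- tfs[[which(vapply(tfs, function(tf) tf$comp == "pat", logical(1)))]]
      mat_tf <- tfs[[which(vapply(tfs, function(tf) tf$comp == "mat", logical(1)))]]
      U <- matrix(u, nrow = sp$H, byrow = TRUE)  # U[hp, hm]
      R <- crossprod(A, U %*% A)                 # t(A) %*% U %*% A
      new_factor <- list(vars = c(pat_tf$parent, mat_tf$parent), tab = R)
    } else {
      facs <- c(list(list(vars = x, tab = u)),
                lapply(tfs, dense_trans), generics[my_gen_i])
      new_factor <- eliminate_var(facs, x, G)
    }

    trans[my_trans_i] <- NULL
    generics[all_gen_i] <- NULL
    alive[x] <- FALSE

    if (is.null(new_factor$vars) || length(new_factor$vars) == 0L) {
      s <- as.numeric(new_factor$tab)
      if (s <= 0) return(structure(-Inf, diagnostic = "zero-probability data"))
      logshift <- logshift + log10(s)
    } else {
      s <- max(new_factor$tab)
      if (s <= 0) return(structure(-Inf, diagnostic = "zero-probability data"))
      new_factor$tab <- new_factor$tab / s
      logshift <- logshift + log10(s)
      generics[[length(generics) + 1L]] <- new_factor
    }
  }
  # all variables gone; any remaining generic factors are scalars
  for (gf in generics) logshift <- logshift + log10(as.numeric(gf$tab))
  logshift
}

# multiply factors sharing variable x and sum x out; dense array join
eliminate_var <- function(facs, x, G) {
  union_vars <- unique(unlist(lapply(facs, `[[`, "vars")))
  union_vars <- c(x, setdiff(union_vars, x))  # x first for fast marginalisation
  u <- length(union_vars)
  res <- array(1, dim = rep(G, u))
  for (f in facs) {
    len <- length(f$vars)
    others <- setdiff(union_vars, f$vars)
    full <- array(as.numeric(f$tab), dim = rep(G, u))  # dims: f$vars then others
    perm <- match(union_vars, c(f$vars, others))
    res <- res * aperm(full, perm)
  }
  if (u == 1L) return(list(vars = integer(0), tab = sum(res)))
  dim(res) <- c(G, G^(u - 1L))
  list(vars = union_vars[-1], tab = array(colSums(res), dim = rep(G, u - 1L)))
}

#' Brute-force two-point log10-likelihood (verification oracle)
#'
#' Exact sum over all joint ordered haplotype-pair assignments by depth-first
#' enumeration in parents-before-children order, pruning zero-weight branches.
#' Exponential in pedigree size; refuses pedigrees above `max_members`. Kept
#' deliberately independent of the peeling implementation.
#'
#' @inheritParams pedigree_log_likelihood
#' @param max_members Enumeration size guard (default 10).
#' @return log10 likelihood (`-Inf` for impossible data).
#' @export
brute_force_log_likelihood <- function(ped, marker, theta, model = linkage_model(),
                                       max_members = 10L) {
  if (ped$n > max_members) {
    stop_input("pedigree too large for enumeration (%d members > %d)", ped$n, max_members)
  }
  if (!(is.numeric(theta) && length(theta) == 1L && theta >= 0 && theta <= 0.5)) {
    stop_input("`theta` must be in [0, 0.5]")
  }
  pre <- prepare_two_point(ped, marker, model)
  sp <- pre$sp
  A <- transmission_matrix(sp, theta)
  n <- length(pre$weights)
  # parents-before-children order
  ord <- integer(0); placed <- rep(FALSE, n)
  while (length(ord) < n) {
    ready <- which(!placed & vapply(seq_len(n), function(i) {
      (is.na(pre$fa[i]) || placed[pre$fa[i]]) &&
        (is.na(pre$mo[i]) || placed[pre$mo[i]])
    }, logical(1)))
    ord <- c(ord, ready[1]); placed[ready[1]] <- TRUE
  }
  assign_g <- integer(n)
  recurse <- function(pos) {
    if (pos > n) return(1)
    i <- ord[pos]
    w <- pre$weights[[i]]
    total <- 0
    if (is.na(pre$fa[i])) {
      for (g in which(w > 0)) {
        assign_g[i] <<- g
        total <- total + w[g] * recurse(pos + 1L)
      }
    } else {
      gF <- assign_g[pre$fa[i]]; gM <- assign_g[pre$mo[i]]
      for (hp in which(A[, gF] > 0)) {
        for (hm in which(A[, gM] > 0)) {
          g <- (hp - 1L) * sp$H + hm
          wg <- w[g] * A[hp, gF] * A[hm, gM]
          if (wg > 0) {
            assign_g[i] <<- g
            total <- total + wg * recurse(pos + 1L)
          }
        }
      }
    }
    total
  }
  L <- recurse(1L)
  if (L <= 0) return(structure(-Inf, diagnostic = "zero-probability data"))
  log10(L)
}

#' Two-point LOD curve over a grid of recombination fractions
#'
#' `LOD(theta) = log10 L(theta) - log10 L(0.5)`; by construction the curve is
#' exactly 0 at `theta = 0.5`. Reports the grid argmax and maximum.
#'
#' @inheritParams pedigree_log_likelihood
#' @param theta_grid Grid in `[0, 0.5]`; must include 0.5 (default
#'   `seq(0, 0.5, by = 0.01)`).
#' @return An object of class `lod_curve`: data.frame (`theta`, `lod`) plus
#'   `theta_max`, `lod_max`.
#' @export
lod_curve <- function(ped, marker, model = linkage_model(),
                      theta_grid = seq(0, 0.5, by = 0.01)) {
  theta_grid <- sort(unique(as.numeric(theta_grid)))
  if (any(theta_grid < 0 | theta_grid > 0.5)) stop_input("theta grid must lie in [0, 0.5]")
  if (!any(theta_grid == 0.5)) stop_input("theta grid must include 0.5")
  ll <- vapply(theta_grid, function(th) {
    as.numeric(pedigree_log_likelihood(ped, marker, th, model))
  }, numeric(1))
  ll_null <- ll[theta_grid == 0.5]
  if (!is.finite(ll_null)) {
    stop_input("data impossible under the model at theta = 0.5 (check marker genotypes)")
  }
  lod <- ll - ll_null
  lod[theta_grid == 0.5] <- 0  # exact by definition
  i <- which.max(lod)
  structure(list(curve = data.frame(theta = theta_grid, lod = lod),
                 theta_max = theta_grid[i], lod_max = lod[i]),
            class = "lod_curve")
}

#' Sum LOD curves across independent families
#' @param curves List of `lod_curve` objects sharing one theta grid.
#' @return A combined `lod_curve`.
#' @export
sum_lod_curves <- function(curves) {
  stopifnot(length(curves) >= 1L, all(vapply(curves, inherits, logical(1), "lod_curve")))
  th <- curves[[1]]$curve$theta
  for (cv in curves) {
    if (!identical(cv$curve$theta, th)) stop_input("curves must share one theta grid")
  }
  lod <- Reduce(`+`, lapply(curves, function(cv) cv$curve$lod))
  i <- which.max(lod)
  structure(list(curve = data.frame(theta = th, lod = lod),
                 theta_max = th[i], lod_max = lod[i]),
            class = "lod_curve")
}

#' @export
print.lod_curve <- function(x, ...) {
  cat(sprintf("<lod_curve> %d grid points; max LOD = %.4f at theta = %.2f\n",
              nrow(x$curve), x$lod_max, x$theta_max))
  invisible(x)
}

#' @export
plot.lod_curve <- function(x, ...) {
  plot(x$curve$theta, x$curve$lod, type = "l", xlab = "recombination fraction",
       ylab = "LOD", ...)
  graphics::abline(h = 0, lty = 3)
  graphics::points(x$theta_max, x$lod_max, pch = 19)
  invisible(x)
}
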