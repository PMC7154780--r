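# Independent straightforward re-implementation of the monthly stage chain,
# written directly from the documented model forms without calling any
# package operation. Used as the trajectory oracle.

oracle_run <- function(site, climate, p, state) {
  p <- as.list(p)
  es <- function(t) 0.61078 * exp(17.269 * t / (237.3 + t))
  dim_tab <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  out <- NULL
  age <- state$age; n <- state$n_trees; ws <- state$ws; wf <- state$wf
  wr <- state$wr; asw <- state$asw; wf_debt <- state$wf_debt
  for (i in seq_len(nrow(climate))) {
    yr <- climate$year[i]; mo <- climate$month[i]
    nd <- dim_tab[mo]
    if (mo == 2 && ((yr %% 4 == 0 && yr %% 100 != 0) || yr %% 400 == 0)) {
      nd <- 29
    }
    if (p$leaf_grow > 0) {
      if (mo == p$leaf_grow) { wf <- wf + wf_debt; wf_debt <- 0 }
      if (mo == p$leaf_fall) { wf_debt <- wf_debt + wf; wf <- 0 }
    }
    tav <- (climate$tmin[i] + climate$tmax[i]) / 2
    vpd <- 0.5 * (es(climate$tmax[i]) - es(climate$tmin[i]))
    ft <- if (tav <= p$t_min || tav >= p$t_max) 0 else {
      min(max(((tav - p$t_min) / (p$t_opt - p$t_min)) *
                ((p$t_max - tav) / (p$t_max - p$t_opt))^
                  ((p$t_max - p$t_opt) / (p$t_opt - p$t_min)), 0), 1)
    }
    ffrost <- min(max(1 - p$k_frost * climate$frost_days[i] / nd, 0), 1)
    fvpd <- exp(-p$coeff_cond * vpd * 10)
    fsw <- 1 / (1 + ((1 - min(max(asw / site$asw_max, 0), 1)) /
                       p$sw_const)^p$sw_power)
    fnutr <- 1 - (1 - p$fn0) * (1 - site$fertility_rating)^p$fnn
    fage <- 1 / (1 + ((age / p$max_age) / p$r_age)^p$n_age)
    co2 <- climate$co2[i]
    fax <- p$f_calpha700 / (2 - p$f_calpha700)
    fg0 <- p$f_cg700 / (2 * p$f_cg700 - 1)
    fca <- fax * co2 / (350 * (fax - 1) + co2)
    fcg <- fg0 / (1 + (fg0 - 1) * co2 / 350)
    phys <- fage * min(fvpd, fsw)
    sla <- p$sla1 + (p$sla0 - p$sla1) * exp(-log(2) * (age / p$t_sla)^2)
    lai <- wf * sla * 0.1
    cover <- if (p$full_can_age > 0) min(age / p$full_can_age, 1) else 1
    apar <- 0.5 * climate$srad[i] * nd * (1 - exp(-p$k * lai)) * cover
    gpp <- p$alpha_c * ft * ffrost * fnutr * fca * phys * apar *
      4.6 * 12 / 0.5 * 0.01
    npp <- p$y * gpp
    if (n > 0) {
      dbh <- (ws * 1000 / n / p$a_ws)^(1 / p$n_ws)
      m <- p$m0 + (1 - p$m0) * site$fertility_rating
      pr <- p$p_rx * p$p_rn / (p$p_rn + (p$p_rx - p$p_rn) * phys * m)
      npw <- log(p$pfs20 / p$pfs2) / log(10)
      pfs <- (p$pfs2 / 2^npw) * dbh^npw
      psr <- (1 - pr) / (1 + pfs)
      pf <- 1 - pr - psr
      gf <- if (p$gamma_f1 == p$gamma_f0) p$gamma_f1 else {
        kg <- log(1 + p$gamma_f1 / p$gamma_f0) / p$t_gamma_f
        p$gamma_f1 * p$gamma_f0 /
          (p$gamma_f0 + (p$gamma_f1 - p$gamma_f0) * exp(-kg * age))
      }
      wf <- max(wf + npp * pf - gf * wf, 0)
      wr <- max(wr + npp * pr - p$gamma_r * wr, 0)
      ws <- max(ws + npp * psr, 0)
      # mortality by very fine brute-force bisection
      wsx <- function(nn) p$w_sx1000 * (1000 / nn)^p$thin_power
      if (ws * 1000 / n > wsx(n)) {
        g <- function(nd2) {
          1000 * ws * (1 - p$m_s * nd2 / n) / (n - nd2) - wsx(n - nd2)
        }
        lo <- 0; hi <- 0.95 * n
        for (b in 1:400) {
          mid <- (lo + hi) / 2
          if (g(mid) > 0) lo <- mid else hi <- mid
        }
        nd2 <- hi
        ws <- ws * (1 - p$m_s * nd2 / n)
        wf <- wf * (1 - p$m_f * nd2 / n)
        wr <- wr * (1 - p$m_r * nd2 / n)
        n <- n - nd2
      }
    }
    gc <- max(p$max_cond * min(fvpd, fsw) * fage * fcg *
                min(lai / p$lai_gcx, 1), p$min_cond)
    doy <- c(15, 46, 74, 105, 135, 166, 196, 227, 258, 288, 319, 349)[mo]
    decl <- -23.45 * pi / 180 * cos(2 * pi * (doy + 10) / 365)
    ch <- min(max(-tan(site$latitude * pi / 180) * tan(decl), -1), 1)
    h <- 2 * acos(ch) / (2 * pi) * 86400
    pm <- function(gcx) {
      if (gcx <= 0) return(0)
      nr <- -90 + 0.8 * (climate$srad[i] * 1e6 / h)
      dt <- 1.2 * 2460000 * 0.000622 * (vpd * 10) * p$bl_cond
      max(gcx * (2.2 * nr + dt) / (gcx * (1 + 2.2) + p$bl_cond) /
            2460000 * h, 0)
    }
    intc <- p$max_intcptn * min(lai / p$lai_max_intcptn, 1) * climate$prcp[i]
    tr <- if (gc > 0) pm(gc) * nd else 0
    avail <- max(asw + climate$prcp[i] - intc, 0)
    tr <- min(tr, avail)
    se <- min(pm(p$soil_cond * exp(-p$k * lai)) * nd, max(avail - tr, 0))
    raw <- asw + climate$prcp[i] - intc - tr - se
    asw <- min(max(raw, 0), site$asw_max)
    age <- age + 1 / 12
    sla2 <- p$sla1 + (p$sla0 - p$sla1) * exp(-log(2) * (age / p$t_sla)^2)
    dbh2 <- if (n > 0) (ws * 1000 / n / p$a_ws)^(1 / p$n_ws) else 0
    out <- rbind(out, data.frame(
      year = yr, month = mo, age = age, n_trees = n, ws = ws, wf = wf,
      wr = wr, asw = asw, lai = wf * sla2 * 0.1, dbh = dbh2,
      gpp = gpp, npp = npp,
      transpiration = tr, soil_evap = se, interception = intc,
      runoff = max(raw - site$asw_max, 0)
    ))
  }
  out
}
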