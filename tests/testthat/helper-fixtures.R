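# Shared fixtures: the reference 29 kg animal and default lung mechanics.

ref_params <- function(...) gas_params(mass = 29, ...)
ref_mech <- function() respiratory_mechanics()

vc_settings <- function(rr = 12, ie = 1, vt_per_kg = 10, fio2 = 0.33,
                        mass = 29) {
  ventilator_settings("VC", rr = rr, ie_ratio = ie, vt = vt_per_kg * mass,
                      peep = 5, fio2 = fio2)
}

pc_settings <- function(rr = 12, ie = 1, vt_per_kg = 10, fio2 = 0.33,
                        mass = 29, mech = ref_mech()) {
  ti <- breath_timing(rr, ie)[["Ti"]]
  p <- pc_pressure_for_vt(vt_per_kg * mass, mech, ti)
  ventilator_settings("PC", rr = rr, ie_ratio = ie, p_insp = p, peep = 5,
                      fio2 = fio2)
}

# alveolar-channel view of a simulated trace, for pre-transmission statistics
alveolar_channel <- function(tr) {
  sampled_trace(tr$time_s, tr$pao2_alv_mmhg, tr$paw_cmh2o)
}

# Inspired and expired O2 volumes over trace samples `idx`, measured directly
# from the trace: inflow when volume rises (dead-space gas first, at the
# end-expiratory alveolar composition), outflow at alveolar composition when
# volume falls.
measure_o2_flux <- function(tr, fio2, params, idx) {
  phase <- attr(tr, "phase")
  fa <- tr$pao2_alv_mmhg / (params$pb - params$ph2o)
  vd <- params$vd_per_kg * params$mass
  insp_o2 <- 0; exp_o2 <- 0; cum <- Inf; fa_ee <- NA
  for (i in idx) {
    dv <- tr$volume_ml[i] - tr$volume_ml[i - 1]
    if (phase[i] == "INSP" && phase[i - 1] != "INSP") {
      cum <- 0; fa_ee <- fa[i - 1]
    }
    if (dv > 0) {
      fin <- if (cum >= vd) fio2
             else if (cum + dv <= vd) fa_ee
             else (fa_ee * (vd - cum) + fio2 * (dv - (vd - cum))) / dv
      insp_o2 <- insp_o2 + fin * dv
      cum <- cum + dv
    } else if (dv < 0) exp_o2 <- exp_o2 - fa[i - 1] * dv
  }
  list(insp = insp_o2, exp = exp_o2)
}
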