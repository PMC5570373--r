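# Unit conventions used throughout the package:
#   time ms, length um, volume um^3, concentration uM (glutamate sometimes mM
#   where noted), voltage mV, conductance pS (unitary) / nS (macroscopic),
#   current pA, capacitance pF, channel permeability cm^3/s.

# ions contained in 1 uM * 1 um^3 (Avogadro * 1e-21 mol)
.ions_per_uM_um3 <- 602.2140857

# RT/F in mV at a Celsius temperature
.rt_over_f <- function(temp_c) 0.0861733 * (temp_c + 273.15)
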