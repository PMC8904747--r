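# Default radiobiological parameter set.
# All doses on the EQD2 scale unless noted.

alpha_beta:
  tumor: 10.5       # Gy, squamous cell carcinoma fractionation sensitivity
  skin: 8.8         # Gy, skin late/acute composite endpoint
  chest_wall: 3.5   # Gy, chest wall late endpoint

tcp:                # Poisson-LQ dose-response, head & neck squamous cells
  tcd50: 51.77      # Gy EQD2, uniform dose giving 50% control
  gamma: 2.28       # normalized slope at TCD50

ntcp:               # Lyman-Kutcher-Burman parameter sets
  chest_wall:
    "n": 0.1         # volume-effect exponent
    m: 0.21         # slope
    td50: 68.00     # Gy EQD2
    endpoint: pathological fracture
  skin:
    "n": 0.1
    m: 0.12
    td50: 70.00     # Gy EQD2
    endpoint: necrosis/ulceration

course:             # three-compartment LQ course model defaults
  alpha: 0.25       # Gy^-1, cSCC linear coefficient (beta = alpha / (alpha/beta tumor))
  oer: 2.0          # oxygen enhancement ratio of the hypoxic compartment
  clonogenDensity: 1.0e+7  # clonogens per cm3 (necrotic compartment carries 0)
  oarDoseThreshold: 2      # Gy physical; OAR restricted to >= this dose for NTCP
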