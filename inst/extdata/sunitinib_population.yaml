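# Population pharmacokinetic model for sunitinib and its active
# metabolite N-desethyl sunitinib (SU12662): two-compartment
# disposition with first-order oral absorption, separate models per
# analyte sharing the structural framework.
#
# Typical values are transcribed from the base (covariate-free) model
# of the published population-PK meta-analysis of sunitinib in healthy
# volunteers and oncology patients (Houk et al., Cancer Chemother
# Pharmacol 2010; 66:357-371). All parameters are apparent
# (bioavailability F absorbed). The metabolite is modelled as an
# independently dosed system receiving the parent's nominal dose: its
# apparent parameters are the reported metabolite values scaled by the
# fixed formation fraction (fm = 0.21), which is thereby absorbed into
# CL and the volumes.
#
# Units: ka 1/h; cl L/h; v1, v2 L; q L/h; omega dimensionless (SD of
# log-normal inter-individual variability); sigma_add and loq ng/mL.

parent:                       # sunitinib
  typical:
    ka: 0.195                 # first-order absorption rate, 1/h
    cl: 51.8                  # CL/F, L/h
    v1: 2030                  # central volume V1/F, L
    q: 7.22                   # inter-compartmental clearance Q/F, L/h
    v2: 583                   # peripheral volume V2/F, L
  omega:                      # IIV retained on cl and v1 only
    cl: 0.35
    v1: 0.45
  error:                      # combined residual error; the assay error
    sigma_prop: 0.2           #   magnitudes are working values for
    sigma_add: 1.0            #   simulation, not assay-validated ones
    loq: 10                   # lower limit of quantification, ng/mL

metabolite:                   # N-desethyl sunitinib, dose-referenced
  typical:                    #   (reported value / fm with fm = 0.21)
    ka: 0.195                 # formation treated as first-order input
    cl: 81.4                  # CLm/(F*fm), L/h
    v1: 3020                  # central volume, L
    q: 95.7                   # inter-compartmental clearance, L/h
    v2: 1850                  # peripheral volume, L
  omega:
    cl: 0.40
    v1: 0.50
  error:
    sigma_prop: 0.2
    sigma_add: 1.0
    loq: 10
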