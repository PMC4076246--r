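# Stylized reconstruction of a full two-time-point causal model of
# combined oral contraceptive use (COC) and cervical precancer (CIN) in
# an HIV-positive cohort. Suffixes 0/1 index time points; SP = sexual
# partnership; CD4 = CD4+ cell count (immune status); HAART =
# antiretroviral therapy; U = unknown exogenous causes of every node.
# Exclusions encoded: HPV causes nothing but CIN; COC and condom use do
# not cause HAART; education, SP, COC0, condom use, HIV and HAART have
# no direct edge into CIN (only via HPV, immune status, or late COC).
# This is a synthetic fixture for graph algorithms, not simulated.
U -> edu
U -> SP0
U -> COC0
U -> condom0
U -> grav0
U -> HIV
U -> CD4_0
U -> HAART0
U -> HPV
U -> SP1
U -> COC1
U -> condom1
U -> grav1
U -> CD4_1
U -> HAART1
U -> CIN
edu -> SP0
edu -> COC0
edu -> condom0
edu -> grav0
edu -> SP1
edu -> COC1
edu -> condom1
edu -> grav1
SP0 -> COC0
SP0 -> condom0
SP0 -> grav0
SP0 -> SP1
SP0 -> HPV
COC0 -> condom0
COC0 -> grav0
COC0 -> COC1
COC0 -> HPV
COC0 -> grav1
condom0 -> grav0
condom0 -> condom1
condom0 -> HPV
grav0 -> grav1
grav0 -> COC1
HIV -> CD4_0
CD4_0 -> HAART0
CD4_0 -> CD4_1
CD4_0 -> HPV
HAART0 -> CD4_1
HAART0 -> HAART1
SP1 -> COC1
SP1 -> condom1
COC1 -> grav1
COC1 -> CIN
grav1 -> CIN
CD4_1 -> HAART1
CD4_1 -> CIN
HPV -> CIN
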