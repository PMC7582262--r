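amino_acid,helix_propensity,sheet_propensity,turn_propensity,pka_carboxyl,pka_amine,pka_side_chain,isoelectric_point,carbon_atoms,hydrogen_atoms,nitrogen_atoms,oxygen_atoms,sulfur_atoms,heavy_atoms,total_atoms,residue_mass,surface_area,volume,hydropathy,polarity
A,1.42,0.83,0.66,2.34,9.69,0,6,3,7,1,2,0,6,13,89.09,129,88.6,1.8,8.1
C,0.7,1.19,1.19,1.96,10.28,8.18,5.07,3,7,1,2,1,7,14,121.16,167,108.5,2.5,5.5
D,1.01,0.54,1.46,1.88,9.6,3.65,2.77,4,7,1,4,0,9,16,133.1,193,111.1,-3.5,13
E,1.51,0.37,0.74,2.19,9.67,4.25,3.22,5,9,1,4,0,10,19,147.13,223,138.4,-3.5,12.3
F,1.13,1.38,0.6,1.83,9.13,0,5.48,9,11,1,2,0,12,23,165.19,240,189.9,2.8,5.2
G,0.57,0.75,1.56,2.34,9.6,0,5.97,2,5,1,2,0,5,10,75.07,104,60.1,-0.4,9
H,1,0.87,0.95,1.82,9.17,6,7.59,6,9,3,2,0,11,20,155.15,224,153.2,-3.2,10.4
I,1.08,1.6,0.47,2.36,9.6,0,6.02,6,13,1,2,0,9,22,131.17,197,166.7,4.5,5.2
K,1.16,0.74,1.01,2.18,8.95,10.53,9.74,6,14,2,2,0,10,24,146.19,236,168.6,-3.9,11.3
L,1.21,1.3,0.59,2.36,9.6,0,5.98,6,13,1,2,0,9,22,131.17,201,166.7,3.8,4.9
M,1.45,1.05,0.6,2.28,9.21,0,5.74,5,11,1,2,1,9,20,149.21,224,162.9,1.9,5.7
N,0.67,0.89,1.56,2.02,8.8,0,5.41,4,8,2,3,0,9,17,132.12,195,114.1,-3.5,11.6
P,0.57,0.55,1.52,1.99,10.6,0,6.3,5,9,1,2,0,8,17,115.13,159,112.7,-1.6,8
Q,1.11,1.1,0.98,2.17,9.13,0,5.65,5,10,2,3,0,10,20,146.15,225,143.8,-3.5,10.5
R,0.98,0.93,0.95,2.17,9.04,12.48,10.76,6,14,4,2,0,12,26,174.2,274,173.4,-4.5,10.5
S,0.77,0.75,1.43,2.21,9.15,0,5.68,3,7,1,3,0,7,14,105.09,155,89,-0.8,9.2
T,0.83,1.19,0.96,2.09,9.1,0,5.6,4,9,1,3,0,8,17,119.12,172,116.1,-0.7,8.6
V,1.06,1.7,0.5,2.32,9.62,0,5.96,5,11,1,2,0,8,19,117.15,174,140,4.2,5.9
W,1.08,1.37,0.96,2.83,9.39,0,5.89,11,12,2,2,0,15,27,204.23,285,227.8,-0.9,5.4
Y,0.69,1.47,1.14,2.2,9.11,10.07,5.66,9,11,1,3,0,13,24,181.19,263,193.6,-1.3,6.2
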