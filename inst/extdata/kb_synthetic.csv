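,A,G,V,L,I,P,F,M,W,C,D,E,R,K,H,N,Q,S,T,Y
A,-4.91,,,,,,,,,,,,,,,,,,,
G,-4.06,-3.2,,,,,,,,,,,,,,,,,,
V,-5.85,-4.99,-6.79,,,,,,,,,,,,,,,,,
L,-5.69,-4.84,-6.63,-6.47,,,,,,,,,,,,,,,,
I,-5.97,-5.11,-6.9,-6.75,-7.02,,,,,,,,,,,,,,,
P,-3.59,-2.73,-4.52,-4.37,-4.64,-2.26,,,,,,,,,,,,,,
F,-5.3,-4.45,-6.24,-6.08,-6.36,-3.98,-5.69,,,,,,,,,,,,,
M,-4.95,-4.1,-5.89,-5.73,-6.01,-3.63,-5.34,-4.99,,,,,,,,,,,,
W,-3.86,-3,-4.8,-4.64,-4.91,-2.54,-4.25,-3.9,-2.81,,,,,,,,,,,
C,-5.19,-4.33,-6.12,-5.97,-6.24,-3.86,-5.58,-5.23,-4.13,-5.46,,,,,,,,,,
D,-2.85,-1.99,-3.78,-3.63,-3.9,-1.52,-3.24,-2.89,-1.79,-3.12,0.02,,,,,,,,,
E,-2.85,-1.99,-3.78,-3.63,-3.9,-1.52,-3.24,-2.89,-1.79,-3.12,0.02,0.02,,,,,,,,
R,-2.46,-1.6,-3.39,-3.24,-3.51,-1.13,-2.85,-2.5,-1.4,-2.73,-1.19,-1.19,0.8,,,,,,,
K,-2.69,-1.83,-3.63,-3.47,-3.74,-1.36,-3.08,-2.73,-1.64,-2.96,-1.42,-1.42,0.57,0.33,,,,,,
H,-2.96,-2.11,-3.9,-3.74,-4.02,-1.64,-3.35,-3,-1.91,-3.24,-0.9,-0.9,-0.51,-0.74,-1.01,,,,,
N,-2.85,-1.99,-3.78,-3.63,-3.9,-1.52,-3.24,-2.89,-1.79,-3.12,-0.78,-0.78,-0.39,-0.62,-0.9,-0.78,,,,
Q,-2.85,-1.99,-3.78,-3.63,-3.9,-1.52,-3.24,-2.89,-1.79,-3.12,-0.78,-0.78,-0.39,-0.62,-0.9,-0.78,-0.78,,,
S,-3.9,-3.04,-4.84,-4.68,-4.95,-2.57,-4.29,-3.94,-2.85,-4.17,-1.83,-1.83,-1.44,-1.68,-1.95,-1.83,-1.83,-2.89,,
T,-3.94,-3.08,-4.88,-4.72,-4.99,-2.61,-4.33,-3.98,-2.89,-4.21,-1.87,-1.87,-1.48,-1.72,-1.99,-1.87,-1.87,-2.93,-2.96,
Y,-3.7,-2.85,-4.64,-4.48,-4.76,-2.38,-4.1,-3.74,-2.65,-3.98,-1.64,-1.64,-1.25,-1.48,-1.76,-1.64,-1.64,-2.69,-2.73,-2.5
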