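analysis
blast
cell
cycle
graph
network
tool
program
data
gene
genome
protein
sequence
structure
model
method
result
value
table
figure
sample
test
run
map
link
tree
path
score
set
list
base
core
find
mark
scan
tag
mine
fold
dot
act
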