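paciente
relata
refere
apresenta
queixa
dores
cabeca
tomando
medicacao
receita
renovada
comprimido
capsula
gotas
xarope
pela
manha
tarde
noite
antes
depois
durante
refeicao
jejum
vezes
diariamente
semana
meses
retorno
consulta
exame
sangue
pressao
arterial
controlada
elevada
febre
tosse
gripe
resfriado
garganta
ouvido
estomago
nausea
vomito
diarreia
alergia
coceira
pele
ferida
curativo
vacina
aplicada
dose
ajustada
suspensa
iniciada
mantida
orientado
orientacoes
dieta
alimentacao
exercicio
caminhada
sono
ansiedade
tristeza
humor
melhora
piora
queixas
negadas
familia
filho
filha
esposa
marido
trabalho
escola
idoso
crianca
gestante
amamentando
historico
cirurgia
internacao
hospital
encaminhado
especialista
cardiologia
psiquiatria
avaliacao
resultado
normal
alterado
solicitado
aguardando
segue
acompanhamento
unidade
posto
saude
agente
visita
domiciliar
telefone
contato
falta
faltou
remarcado
horario
agenda
quadro
estavel
evolucao
boa
ruim
uso
continuo
correto
irregular
abandono
tratamento
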